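# Peak kinetics of cycle-averaged ramp responses.
#
# The two statistics reported per ROI are (1) LUX-at-half-max, the
# stimulus luminance at the moment the response first reaches 50% of
# its peak, and (2) width-at-half-max, the response duration at 50% of
# peak. Both hinge on detecting significant peaks by topographic
# prominence on the *cyclic* averaged response, so a peak straddling
# the cycle seam (typical of OFF responses, which peak at minimum
# luminance) is found exactly once.

#' Detect significant peaks in a cycle-averaged response
#'
#' Finds local maxima of the cyclic response and keeps those whose
#' topographic prominence exceeds `min_prominence` (0.75 z-units by
#' default). Prominence is the standard lowest-contour definition,
#' evaluated on the cyclic domain: from each peak, descend in both
#' directions until strictly higher ground (or a full wrap); the key
#' col is the higher of the two path minima. Plateaus (runs of tied
#' samples strictly above both neighbours) count as one peak at the
#' plateau centre.
#'
#' Half-max crossings flanking each peak are located by linear
#' interpolation at level `baseline + (height - baseline) / 2`, where
#' the baseline is the minimum of the cycle response (or
#' `height - prominence / 2` with `baseline = "prominence"`). Crossing
#' times are unwrapped around the peak, so `left_half_t < t_peak <
#' right_half_t` always holds; fold with [cycle_fold()] to map them
#' back into the cycle.
#'
#' @param cycles tibble from [cycle_average()] (`roi`, `t_cycle`, `z`).
#' @param min_prominence significance threshold in z-units.
#' @param baseline `"min"` (default) or `"prominence"`; see Details.
#' @return A tibble with one row per significant peak: `roi`, `peak`,
#'   `t_peak`, `height`, `prominence`, `left_half_t`, `right_half_t`,
#'   `width`, `truncated`.
#' @export
find_cycle_peaks <- function(cycles, min_prominence = 0.75,
                             baseline = c("min", "prominence")) {
  baseline <- match.arg(baseline)
  cycles |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$t_cycle)
      peaks_one_cycle(df$z, df$t_cycle, min_prominence, baseline)
    }) |>
    dplyr::ungroup()
}

# Peak detection on one cyclic vector. Times are assumed sorted and
# (close to) regularly spaced over one cycle period.
peaks_one_cycle <- function(z, t, min_prominence, baseline = "min") {
  n <- length(z)
  if (n < 3) abort("cycle response must have at least 3 samples")
  dt <- t[2] - t[1]
  period <- n * dt

  cand <- cyclic_local_maxima(z)
  out <- list()
  for (p in cand) {
    prom <- cyclic_prominence(z, p)
    if (!(prom > min_prominence)) next
    height <- z[p]
    base <- if (baseline == "min") min(z) else height - prom / 2
    level <- base + (height - base) / 2
    cross <- half_crossings(z, t, p, level, period)
    out[[length(out) + 1]] <- tibble::tibble(
      t_peak = t[p], height = height, prominence = prom,
      left_half_t = cross$left, right_half_t = cross$right,
      truncated = cross$truncated
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      peak = integer(), t_peak = numeric(), height = numeric(),
      prominence = numeric(), left_half_t = numeric(),
      right_half_t = numeric(), width = numeric(), truncated = logical()
    ))
  }
  res <- dplyr::bind_rows(out) |> dplyr::arrange(.data$t_peak)
  res$peak <- seq_len(nrow(res))
  res$width <- res$right_half_t - res$left_half_t
  dplyr::select(res, "peak", "t_peak", "height", "prominence",
                "left_half_t", "right_half_t", "width", "truncated")
}

# Indices of cyclic local maxima; a plateau contributes its centre
# index (rounded towards the start). A constant signal has none.
cyclic_local_maxima <- function(z) {
  n <- length(z)
  if (diff(range(z)) == 0) return(integer())
  idx <- integer()
  i <- 1L
  visited <- rep(FALSE, n)
  while (i <= n) {
    if (visited[i]) { i <- i + 1L; next }
    # maximal cyclic run of values equal to z[i]
    run <- i
    j <- i
    repeat {
      nxt <- (j %% n) + 1L
      if (z[nxt] != z[i] || nxt == i) break
      run <- c(run, nxt)
      j <- nxt
    }
    k <- i
    repeat {
      prv <- ((k - 2L) %% n) + 1L
      if (z[prv] != z[i] || prv %in% run) break
      run <- c(prv, run)
      k <- prv
    }
    visited[run] <- TRUE
    before <- ((run[1] - 2L) %% n) + 1L
    after <- (run[length(run)] %% n) + 1L
    if (length(run) < n && z[before] < z[i] && z[after] < z[i]) {
      idx <- c(idx, run[ceiling(length(run) / 2)])
    }
    i <- i + 1L
  }
  sort(unique(idx))
}

# Topographic prominence of peak index p on cyclic z.
cyclic_prominence <- function(z, p) {
  n <- length(z)
  v <- z[p]
  walk_min <- function(step) {
    m <- v
    i <- p
    for (s in seq_len(n - 1)) {
      i <- ((i - 1L + step) %% n) + 1L
      if (z[i] > v) return(m)
      m <- min(m, z[i])
    }
    m  # full wrap without higher ground
  }
  v - max(walk_min(1L), walk_min(-1L))
}

# First crossings of `level` on either side of peak p, linearly
# interpolated; times unwrapped around t[p]. A search that wraps the
# whole cycle without crossing is truncated at one period.
half_crossings <- function(z, t, p, level, period) {
  n <- length(z)
  find_side <- function(step) {
    i <- p
    for (s in seq_len(n)) {
      j <- ((i - 1L + step) %% n) + 1L
      tj <- t[p] + step * s * (period / n)
      if (z[j] <= level) {
        zi <- z[i]
        ti <- tj - step * (period / n)
        frac <- if (zi == z[j]) 0 else (zi - level) / (zi - z[j])
        return(list(t = ti + step * frac * (period / n), truncated = FALSE))
      }
      i <- j
    }
    list(t = t[p] + step * period, truncated = TRUE)
  }
  left <- find_side(-1L)
  right <- find_side(1L)
  list(left = left$t, right = right$t,
       truncated = left$truncated || right$truncated)
}

#' LUX at half-max of the dominant response peak
#'
#' For each ROI, selects the most prominent significant peak (for DUAL
#' responses this is the OFF-phase peak by construction of the class)
#' and maps the rising half-max crossing that precedes it through the
#' luminance ramp, giving the light intensity at which the response
#' reached 50% of its peak.
#'
#' @param peaks tibble from [find_cycle_peaks()].
#' @param stim the [ramp_stimulus()] the responses were recorded under.
#' @return A tibble `roi`, `lux_at_half_max`, `t_half`, `phase`
#'   (stimulus phase at the crossing). ROIs with no significant peak
#'   are absent; join against your ROI list to recover them as `NA`.
#' @export
lux_at_half_max <- function(peaks, stim) {
  peaks |>
    dplyr::group_by(.data$roi) |>
    dplyr::slice_max(.data$prominence, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      t_half = .data$left_half_t %% (2 * stim$ramp_s),
      lux_at_half_max = lux_at_tau(stim, .data$t_half),
      phase = ifelse(.data$t_half < stim$ramp_s, "RISING", "FALLING")
    ) |>
    dplyr::select("roi", "lux_at_half_max", "t_half", "phase")
}

#' Width at half-max of the response
#'
#' Response duration at 50% of peak. ROIs with several significant
#' peaks (DUAL responses) report the arithmetic mean of the individual
#' peak widths.
#'
#' @param peaks tibble from [find_cycle_peaks()].
#' @return A tibble `roi`, `width_at_half_max`, `n_peaks`, `truncated`.
#' @export
width_at_half_max <- function(peaks) {
  peaks |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(
      width_at_half_max = mean(.data$width),
      n_peaks = dplyr::n(),
      truncated = any(.data$truncated),
      .groups = "drop"
    )
}

#' Per-ROI kinetics summary
#'
#' Runs [find_cycle_peaks()] and combines [lux_at_half_max()] and
#' [width_at_half_max()] into one table. ROIs without a significant
#' peak get `NA` kinetics and `n_peaks = 0`.
#'
#' @inheritParams find_cycle_peaks
#' @param stim the [ramp_stimulus()].
#' @return A tibble `roi`, `n_peaks`, `lux_at_half_max`,
#'   `width_at_half_max`, `class_hint` (`"single-peak"`, `"dual-peak"`
#'   or `"no-peak"`).
#' @export
kinetics_summary <- function(cycles, stim, min_prominence = 0.75,
                             baseline = c("min", "prominence")) {
  peaks <- find_cycle_peaks(cycles, min_prominence, baseline)
  rois <- tibble::tibble(roi = unique(cycles$roi))
  if (nrow(peaks) == 0) {
    return(dplyr::mutate(rois, n_peaks = 0L, lux_at_half_max = NA_real_,
                         width_at_half_max = NA_real_, class_hint = "no-peak"))
  }
  lux <- lux_at_half_max(peaks, stim)
  wid <- width_at_half_max(peaks)
  rois |>
    dplyr::left_join(dplyr::select(lux, "roi", "lux_at_half_max"), by = "roi") |>
    dplyr::left_join(dplyr::select(wid, "roi", "width_at_half_max", "n_peaks"),
                     by = "roi") |>
    dplyr::mutate(
      n_peaks = dplyr::coalesce(.data$n_peaks, 0L),
      class_hint = dplyr::case_when(
        .data$n_peaks == 0 ~ "no-peak",
        .data$n_peaks == 1 ~ "single-peak",
        TRUE ~ "dual-peak"
      )
    )
}
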
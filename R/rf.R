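# Receptive-field mapping from checkerboard trials.

#' Build receptive-field maps from trial responses
#'
#' For each unit, z-scores the whole recording -- mean and SD of the
#' entire trace, pooling both hemifield sessions, deliberately
#' distinct from the stimulus-window normalisation used for ramp
#' traces -- and takes, per trial, the maximum z between square onset
#' and `lag_s` seconds after square offset: the peak signal during
#' each presentation, with a short lag to catch the slow indicator.
#' The value is placed at the trial's grid position, so the map does
#' not depend on the pseudorandom presentation order. Pooling both
#' sessions matters: it keeps the z of a silent hemifield near zero
#' for units that respond only on the other side.
#'
#' @param responses long tibble `unit`, `side`, `time`, `value`
#'   (optionally `tier`), spanning the full schedule per unit/side.
#' @param schedules named list of [trial_schedule()] tibbles, one per
#'   side appearing in `responses`.
#' @param lag_s response window extension past square offset, seconds.
#' @return A tibble `unit` (+ `tier`), `side`, `trial`, `row`, `col`,
#'   `z`.
#' @export
rf_map <- function(responses, schedules, lag_s = 2) {
  has_tier <- "tier" %in% names(responses)
  keys <- c(if (has_tier) "tier", "unit")
  responses |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      mu <- mean(df$value)
      sigma <- sd(df$value)
      z_all <- if (!is.finite(sigma) || sigma == 0) rep(0, nrow(df))
        else (df$value - mu) / sigma
      purrr::map(unique(df$side), function(s) {
        sched <- schedules[[s]]
        if (is.null(sched)) abort(sprintf("no schedule for side '%s'", s))
        sel <- df$side == s
        tt <- df$time[sel]
        z <- z_all[sel]
        purrr::pmap(sched, function(trial, row, col, t_on, t_off) {
          inw <- tt >= t_on - 1e-9 & tt <= t_off + lag_s + 1e-9
          if (!any(inw)) abort(sprintf("no samples in trial %d window", trial))
          tibble::tibble(side = s, trial = trial, row = row, col = col,
                         z = max(z[inw]))
        }) |> purrr::list_rbind()
      }) |> purrr::list_rbind()
    }) |>
    dplyr::ungroup()
}

#' Receptive-field size
#'
#' Counts stimulus positions whose response reaches `z_min` (inclusive,
#' `z >= 1.5` by default) per unit and hemifield.
#'
#' @param map tibble from [rf_map()].
#' @param z_min threshold in z-units.
#' @return A tibble `unit` (+ `tier`), `side`, `size`.
#' @export
rf_size <- function(map, z_min = 1.5) {
  keys <- intersect(c("tier", "unit", "side"), names(map))
  map |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(size = sum(.data$z >= z_min), .groups = "drop")
}

#' Binocular receptive-field summary
#'
#' Combines the two hemifield maps of each unit into RF sizes, the
#' contra/ipsi size ratio (undefined for monocular units), a
#' binocularity call (suprathreshold positions in both hemifields),
#' and the number of 8-connected suprathreshold components per
#' hemifield (compound-RF descriptor).
#'
#' @param map tibble from [rf_map()] whose `side` values are
#'   `"contra"` and `"ipsi"`.
#' @param z_min threshold in z-units.
#' @return A tibble `unit` (+ `tier`), `size_contra`, `size_ipsi`,
#'   `size_total`, `ratio`, `binocular`, `n_components_contra`,
#'   `n_components_ipsi`.
#' @export
binocular_summary <- function(map, z_min = 1.5) {
  if (!all(unique(map$side) %in% c("contra", "ipsi"))) {
    abort("`map$side` must be 'contra'/'ipsi' for a binocular summary")
  }
  keys <- intersect(c("tier", "unit"), names(map))
  map |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      side_stats <- function(s) {
        d <- df[df$side == s, ]
        if (nrow(d) == 0) return(list(size = 0L, ncomp = 0L))
        grid <- matrix(FALSE, max(d$row), max(d$col))
        grid[cbind(d$row, d$col)] <- d$z >= z_min
        list(size = sum(grid), ncomp = max(label_components(grid, 8)))
      }
      co <- side_stats("contra")
      ip <- side_stats("ipsi")
      tibble::tibble(
        size_contra = co$size, size_ipsi = ip$size,
        size_total = co$size + ip$size,
        ratio = if (ip$size > 0) co$size / ip$size else NA_real_,
        binocular = co$size >= 1 && ip$size >= 1,
        n_components_contra = co$ncomp, n_components_ipsi = ip$ncomp
      )
    }) |>
    dplyr::ungroup()
}

#' Compare receptive-field size across unit tiers
#'
#' Per-tier mean total RF size with SEM, plus a flag for the expected
#' convergence ordering: pyramidal neurons larger than SM-projecting
#' torus longitudinalis neurons, which are at least as large as
#' retinal ganglion cell inputs.
#'
#' @param summaries tibble from [binocular_summary()] including a
#'   `tier` column with values among `"RGC"`, `"SMTL"`, `"PyrN"`.
#' @return An object of class `tier_comparison`: `stats` (tibble
#'   `tier`, `n`, `mean_size`, `sem`) and `ordering` (logical,
#'   `mean(PyrN) > mean(SMTL) >= mean(RGC)`). Supports [tidy()] and
#'   [glance()].
#' @export
tier_comparison <- function(summaries) {
  if (!"tier" %in% names(summaries)) abort("`summaries` needs a `tier` column")
  stats <- summaries |>
    dplyr::group_by(.data$tier) |>
    dplyr::summarise(n = dplyr::n(), mean_size = mean(.data$size_total),
                     sem = sd(.data$size_total) / sqrt(dplyr::n()),
                     .groups = "drop")
  if (any(stats$n == 0)) abort("empty tier")
  get <- function(t) stats$mean_size[stats$tier == t]
  ordering <- length(get("PyrN")) == 1 && length(get("SMTL")) == 1 &&
    length(get("RGC")) == 1 &&
    get("PyrN") > get("SMTL") && get("SMTL") >= get("RGC")
  structure(list(stats = stats, ordering = ordering),
            class = "tier_comparison")
}

#' @export
print.tier_comparison <- function(x, ...) {
  print(x$stats)
  cat(sprintf("convergence ordering PyrN > SMTL >= RGC: %s\n", x$ordering))
  invisible(x)
}
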
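#' Z-score fluorescence traces over the stimulus window
#'
#' Normalises each ROI's trace as `z = (x - mu) / sigma`, where `mu`
#' and `sigma` are the mean and standard deviation of the fluorescence
#' from stimulus onset until stimulus end. All samples (including any
#' outside the window) are transformed with the window statistics.
#' `sigma` uses the population (N) denominator by default.
#'
#' Constant traces (`sigma` below `tol`) cannot be normalised; their
#' `z` is set to 0 and they are flagged in the `flat` column, which the
#' responsiveness gate treats as nonresponsive.
#'
#' @param traces long tibble with columns `roi`, `time`, `value` (one
#'   row per ROI sample).
#' @param stim a [ramp_stimulus()] defining the normalisation window.
#' @param denominator `"population"` (divide by N, the default) or
#'   `"sample"` (N - 1).
#' @param tol sigma below which a trace is declared constant.
#' @return The input tibble with added columns `z` and `flat`.
#' @examples
#' stim <- ramp_stimulus(n_cycles = 1)
#' tr <- tibble::tibble(roi = "a", time = 0:19, value = sin(0:19))
#' zscore_traces(tr, stim)
#' @export
zscore_traces <- function(traces, stim, denominator = c("population", "sample"),
                          tol = 1e-12) {
  denominator <- match.arg(denominator)
  check_trace_table(traces)
  t_end <- stim$t_start + stim_duration(stim)
  traces |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_modify(function(df, key) {
      inw <- df$time >= stim$t_start - 1e-9 & df$time <= t_end + 1e-9
      if (sum(inw) < 2) abort("stimulus window must contain at least 2 samples")
      x <- df$value[inw]
      mu <- mean(x)
      sigma <- sd(x)
      if (denominator == "population") {
        sigma <- sigma * sqrt((length(x) - 1) / length(x))
      }
      if (!is.finite(sigma) || sigma < tol) {
        df$z <- 0
        df$flat <- TRUE
      } else {
        df$z <- (df$value - mu) / sigma
        df$flat <- FALSE
      }
      df
    }) |>
    dplyr::ungroup()
}

#' Gate responsiveness on the z-scored trace
#'
#' An ROI whose z-score never exceeds the bounds of +/- `bound` over the
#' stimulus window is flagged nonresponsive; flat traces are always
#' nonresponsive. The bound is exclusive: a trace must leave the band
#' (`|z| > bound`) to count as responsive.
#'
#' @param ztraces output of [zscore_traces()].
#' @param stim a [ramp_stimulus()]; only samples inside the stimulus
#'   window are examined.
#' @param bound gate half-width in z-units (0.5 by default).
#' @return A tibble with one row per ROI: `roi`, `max_abs_z`,
#'   `responsive` (logical).
#' @export
gate_responsiveness <- function(ztraces, stim, bound = 0.5) {
  t_end <- stim$t_start + stim_duration(stim)
  ztraces |>
    dplyr::filter(.data$time >= stim$t_start - 1e-9,
                  .data$time <= t_end + 1e-9) |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(
      max_abs_z = max(abs(.data$z)),
      responsive = !any(.data$flat) & max(abs(.data$z)) > bound,
      .groups = "drop"
    )
}

#' Average the response over stimulus cycles
#'
#' Folds each ROI's z-scored samples into cycle time with
#' [cycle_fold()] and averages pointwise across cycles, yielding the
#' per-cycle mean response used by all downstream kinetics and
#' classification. Samples are aligned by their folded time on a
#' regular grid of `round(2 * ramp_s * rate_hz)` bins (nearest-bin
#' assignment, no interpolation); samples from incomplete trailing
#' cycles and outside the stimulus window are discarded.
#'
#' @param ztraces output of [zscore_traces()].
#' @param stim a [ramp_stimulus()].
#' @param rate_hz sampling rate. If `NULL`, inferred from the median
#'   sample spacing.
#' @param drop_first_cycle drop the first (indicator-transient) cycle
#'   before averaging; default keeps it.
#' @return A tibble with columns `roi`, `t_cycle`, `z` (cycle-mean) and
#'   `n_cycles` (complete cycles averaged).
#' @export
cycle_average <- function(ztraces, stim, rate_hz = NULL,
                          drop_first_cycle = FALSE) {
  if (is.null(rate_hz)) {
    dt <- median(diff(sort(unique(ztraces$time))))
    rate_hz <- 1 / dt
  }
  period <- 2 * stim$ramp_s
  n_bins <- round(period * rate_hz)
  if (n_bins < 2) abort("sampling rate too low to resolve a cycle")
  t_end <- stim$t_start + stim_duration(stim)

  df <- ztraces |>
    dplyr::filter(.data$time >= stim$t_start - 1e-9,
                  .data$time < t_end - 1e-9) |>
    dplyr::mutate(
      cycle = floor((.data$time - stim$t_start) / period + 1e-9),
      bin = (round(cycle_fold(stim, .data$time) * rate_hz) %% n_bins)
    )
  if (nrow(df) == 0) abort("no complete stimulus cycle available to average")
  # complete cycles actually covered by the data; drop partial trailing
  n_complete <- floor((max(df$time) - stim$t_start + 1.5 / rate_hz) / period)
  if (n_complete - as.integer(drop_first_cycle) < 1) {
    abort("no complete stimulus cycle available to average")
  }
  df |>
    dplyr::filter(.data$cycle < n_complete,
                  if (drop_first_cycle) .data$cycle >= 1 else TRUE) |>
    dplyr::group_by(.data$roi, .data$bin) |>
    dplyr::summarise(z = mean(.data$z), n_cycles = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(t_cycle = .data$bin / rate_hz) |>
    dplyr::select("roi", "t_cycle", "z", "n_cycles") |>
    dplyr::arrange(.data$roi, .data$t_cycle)
}

check_trace_table <- function(traces) {
  need <- c("roi", "time", "value")
  missing <- setdiff(need, names(traces))
  if (length(missing) > 0) {
    abort(sprintf("trace table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(traces)
}
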
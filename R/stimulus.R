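#' Triangular luminance-ramp stimulus
#'
#' Describes a whole-field stimulus whose luminance rises linearly from
#' `min_lux` to `max_lux` over `ramp_s` seconds and falls back linearly
#' over the next `ramp_s` seconds, repeated for `n_cycles` cycles. One
#' cycle therefore lasts `2 * ramp_s` seconds (20 s for the standard
#' 10 s ramp, 60 s for the 30 s ramp) and starts at the minimum.
#'
#' @param min_lux,max_lux luminance bounds in LUX; `min_lux < max_lux`.
#'   Defaults are the 0.4--32 LUX range used for tectal recordings.
#' @param ramp_s duration of one linear leg, seconds.
#' @param n_cycles number of consecutive cycles.
#' @param t_start stimulus onset in recording time, seconds.
#' @return An object of class `ramp_stimulus`.
#' @examples
#' stim <- ramp_stimulus(ramp_s = 10, n_cycles = 3)
#' lux_at(stim, c(0, 5, 10, 25))
#' @export
ramp_stimulus <- function(min_lux = 0.4, max_lux = 32, ramp_s = 10,
                          n_cycles = 1, t_start = 0) {
  if (!(min_lux < max_lux)) abort("`min_lux` must be smaller than `max_lux`.")
  if (ramp_s <= 0) abort("`ramp_s` must be positive.")
  if (n_cycles < 1) abort("`n_cycles` must be at least 1.")
  structure(
    list(min_lux = min_lux, max_lux = max_lux, ramp_s = ramp_s,
         n_cycles = as.integer(n_cycles), t_start = t_start),
    class = "ramp_stimulus"
  )
}

#' @export
print.ramp_stimulus <- function(x, ...) {
  cat(sprintf(
    "<ramp_stimulus> %g-%g LUX, %g s ramps (%g s cycle), %d cycle(s), onset %g s\n",
    x$min_lux, x$max_lux, x$ramp_s, 2 * x$ramp_s, x$n_cycles, x$t_start))
  invisible(x)
}

#' Total stimulus duration in seconds
#' @param stim a [ramp_stimulus()].
#' @return Length of the stimulus window, seconds.
#' @export
stim_duration <- function(stim) 2 * stim$ramp_s * stim$n_cycles

#' Luminance at a time point
#'
#' Evaluates the triangular luminance trajectory. The rising leg covers
#' `[0, ramp_s)` of each cycle and the falling leg `[ramp_s, 2 ramp_s)`,
#' so the phase tag is unambiguous at the extrema: the apex is tagged
#' `FALLING` and the cycle start `RISING`.
#'
#' @param stim a [ramp_stimulus()].
#' @param t time(s) in recording seconds.
#' @return A tibble with columns `t`, `lux`, `phase` (`"RISING"`/`"FALLING"`).
#' @export
lux_at <- function(stim, t) {
  t_end <- stim$t_start + stim_duration(stim)
  if (any(t < stim$t_start - 1e-9) || any(t > t_end + 1e-9)) {
    abort(sprintf("time outside stimulus window [%g, %g]", stim$t_start, t_end))
  }
  tau <- cycle_fold(stim, t)
  rising <- tau < stim$ramp_s
  frac <- ifelse(rising, tau / stim$ramp_s, 2 - tau / stim$ramp_s)
  tibble::tibble(
    t = t,
    lux = stim$min_lux + frac * (stim$max_lux - stim$min_lux),
    phase = ifelse(rising, "RISING", "FALLING")
  )
}

# Vectorised luminance without the window check or tibble wrapper;
# used in inner loops.
lux_at_tau <- function(stim, tau) {
  frac <- ifelse(tau < stim$ramp_s, tau / stim$ramp_s, 2 - tau / stim$ramp_s)
  stim$min_lux + frac * (stim$max_lux - stim$min_lux)
}

#' Fold recording time into cycle time
#'
#' Maps times to seconds within the cycle, `[0, 2 * ramp_s)`. Luminance
#' is invariant under this fold.
#'
#' @inheritParams lux_at
#' @return Numeric vector of folded times.
#' @export
cycle_fold <- function(stim, t) {
  (t - stim$t_start) %% (2 * stim$ramp_s)
}

#' Checkerboard receptive-field mapping stimulus
#'
#' A grid of square flashes presented one at a time in seeded
#' pseudorandom order on one display (hemifield). The default matches
#' the mapping protocol: a 6 x 4 array of 15 degree squares spanning
#' 90 x 60 degrees, each shown for 10 s with a 10 s gap.
#'
#' @param n_cols,n_rows grid dimensions.
#' @param square_deg square side, degrees of visual field.
#' @param present_s,gap_s presentation and inter-trial gap, seconds.
#' @param side which display, `"left"` or `"right"`.
#' @param seed integer seed fixing the pseudorandom presentation order.
#' @param t_start schedule onset in recording time, seconds.
#' @return An object of class `checkerboard_stimulus`.
#' @export
checkerboard_stimulus <- function(n_cols = 6, n_rows = 4, square_deg = 15,
                                  present_s = 10, gap_s = 10,
                                  side = c("left", "right"), seed = 1,
                                  t_start = 0) {
  side <- match.arg(side)
  if (n_cols < 1 || n_rows < 1) abort("grid must have at least one cell")
  if (present_s <= 0 || gap_s < 0) abort("invalid trial timing")
  structure(
    list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
         square_deg = square_deg, present_s = present_s, gap_s = gap_s,
         side = side, seed = as.integer(seed), t_start = t_start,
         span_deg = c(horizontal = n_cols * square_deg,
                      vertical = n_rows * square_deg)),
    class = "checkerboard_stimulus"
  )
}

#' @export
print.checkerboard_stimulus <- function(x, ...) {
  cat(sprintf(
    "<checkerboard_stimulus> %dx%d grid of %g deg squares (%s display), %g s on / %g s off, seed %d\n",
    x$n_cols, x$n_rows, x$square_deg, x$side, x$present_s, x$gap_s, x$seed))
  invisible(x)
}

#' Trial schedule of a checkerboard stimulus
#'
#' Expands the stimulus into one row per presentation: every grid
#' position appears exactly once, in the seeded pseudorandom order, with
#' consecutive onsets spaced by `present_s + gap_s`.
#'
#' @param stim a [checkerboard_stimulus()].
#' @return A tibble with columns `trial`, `row`, `col`, `t_on`, `t_off`.
#' @export
trial_schedule <- function(stim) {
  n <- stim$n_rows * stim$n_cols
  order <- with_seed(stim$seed, sample.int(n))
  period <- stim$present_s + stim$gap_s
  tibble::tibble(
    trial = seq_len(n),
    row = ((order - 1L) %/% stim$n_cols) + 1L,
    col = ((order - 1L) %% stim$n_cols) + 1L,
    t_on = stim$t_start + (seq_len(n) - 1) * period,
    t_off = stim$t_start + (seq_len(n) - 1) * period + stim$present_s
  )
}
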
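# Synthetic GCaMP6s ramp responses with ground truth.
#
# Firing kernels are defined over (luminance, ramp phase) rather than
# time, so the same kernel yields consistent LUX-at-half-max for 10 s
# and 30 s ramps. The noiseless firing rate is convolved with a causal
# double-exponential indicator kernel (slow GCaMP6s by default) and
# i.i.d. Gaussian noise is added.

#' Response kernel of a synthetic unit
#'
#' ON units fire near maximum luminance, OFF units near minimum, and
#' DUAL units carry two luminance-tuned peaks, one on the rising and
#' one on the falling ramp leg, with the falling (OFF-phase) peak more
#' prominent (`dual_ratio < 1` scales the rising-phase peak).
#'
#' @param label `"ON"`, `"OFF"`, `"DUAL"` or `"NONRESPONSIVE"`.
#' @param center_lux luminance of peak firing (per-label defaults:
#'   ON 32, OFF 0.4, DUAL 14 LUX).
#' @param width_lux Gaussian tuning width in LUX.
#' @param amplitude firing-rate scale (arbitrary units; traces are
#'   z-scored downstream, so only ratios to `noise_sd` matter).
#' @param dual_ratio relative amplitude of the rising-phase peak for
#'   DUAL units, in (0, 1).
#' @return An object of class `response_kernel`.
#' @export
response_kernel <- function(label = c("ON", "OFF", "DUAL", "NONRESPONSIVE"),
                            center_lux = NULL, width_lux = 6,
                            amplitude = 1, dual_ratio = 0.6) {
  label <- match.arg(label)
  if (is.null(center_lux)) {
    center_lux <- switch(label, ON = 32, OFF = 0.4, DUAL = 14,
                         NONRESPONSIVE = NA_real_)
  }
  if (label != "NONRESPONSIVE") {
    if (amplitude <= 0) abort("`amplitude` must be positive")
    if (label == "DUAL" && !(dual_ratio > 0 && dual_ratio < 1)) {
      abort("`dual_ratio` must lie in (0, 1)")
    }
  }
  structure(list(label = label, center_lux = center_lux,
                 width_lux = width_lux, amplitude = amplitude,
                 dual_ratio = dual_ratio),
            class = "response_kernel")
}

#' Calcium-indicator model
#'
#' Causal double-exponential impulse response
#' `h(t) = exp(-t / tau_decay) - exp(-t / tau_rise)`, normalised to
#' unit area, applied by discrete convolution at `rate_hz`. Defaults
#' approximate slow GCaMP6s kinetics at the 1--2 Hz acquisition rates
#' used for ramp imaging.
#'
#' @param tau_rise,tau_decay rise and decay time constants, seconds
#'   (`tau_decay > tau_rise > 0`).
#' @param noise_sd standard deviation of additive Gaussian noise, in
#'   units of kernel amplitude.
#' @param rate_hz sampling rate, samples per second.
#' @return An object of class `indicator_spec`.
#' @export
indicator_spec <- function(tau_rise = 0.2, tau_decay = 1.8,
                           noise_sd = 0.2, rate_hz = 2) {
  if (!(tau_decay > tau_rise && tau_rise > 0)) {
    abort("need `tau_decay` > `tau_rise` > 0")
  }
  if (noise_sd < 0 || rate_hz <= 0) abort("invalid indicator parameters")
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay,
                 noise_sd = noise_sd, rate_hz = rate_hz),
            class = "indicator_spec")
}

# Instantaneous firing rate of a kernel along the ramp, at folded
# cycle times tau.
firing_rate_tau <- function(kernel, stim, tau) {
  if (kernel$label == "NONRESPONSIVE") return(rep(0, length(tau)))
  lux <- lux_at_tau(stim, tau)
  g <- function(c) exp(-(lux - c)^2 / (2 * kernel$width_lux^2))
  if (kernel$label == "DUAL") {
    falling <- tau >= stim$ramp_s
    kernel$amplitude * (g(kernel$center_lux) * falling +
                          kernel$dual_ratio * g(kernel$center_lux) * !falling)
  } else {
    kernel$amplitude * g(kernel$center_lux)
  }
}

# Discrete causal convolution with the indicator impulse response
# (unit-area), starting from a zero state.
indicator_convolve <- function(r, indicator) {
  dt <- 1 / indicator$rate_hz
  K <- max(2L, ceiling(6 * indicator$tau_decay / dt) + 1L)
  th <- (seq_len(K) - 1) * dt
  h <- exp(-th / indicator$tau_decay) - exp(-th / indicator$tau_rise)
  h <- h / sum(h)
  full <- stats::convolve(r, rev(h), type = "open")
  full[seq_along(r)]
}

# Noiseless signal evaluated on an arbitrary time grid (recording time).
noiseless_signal <- function(stim, kernel, indicator, t) {
  r <- firing_rate_tau(kernel, stim, cycle_fold(stim, t))
  indicator_convolve(r, indicator)
}

#' Simulate one fluorescence trace
#'
#' Evaluates the kernel's firing rate along the ramp, convolves it with
#' the indicator impulse response and adds Gaussian noise on top of a
#' constant baseline. `NONRESPONSIVE` kernels yield baseline plus
#' noise only.
#'
#' Ground truth (the label and, for responsive kernels, the luminance
#' at which the steady-state noiseless signal crosses 50% of its peak,
#' plus that peak's half-height width) is attached as the `"truth"`
#' attribute, computed on a dense 20 Hz grid independently of the
#' analysis path.
#'
#' @param stim a [ramp_stimulus()].
#' @param kernel a [response_kernel()].
#' @param indicator an [indicator_spec()].
#' @param roi ROI identifier stored in the output.
#' @param baseline constant fluorescence offset.
#' @param seed optional integer seed for the noise draw.
#' @return A tibble `roi`, `time`, `value` with attribute `"truth"`
#'   (a one-row tibble: `roi`, `label`, `lux_half_max`, `width_half`).
#' @export
simulate_trace <- function(stim, kernel, indicator = indicator_spec(),
                           roi = "roi1", baseline = 1, seed = NULL) {
  dt <- 1 / indicator$rate_hz
  t <- seq(stim$t_start, stim$t_start + stim_duration(stim) - dt / 2, by = dt)
  sig <- noiseless_signal(stim, kernel, indicator, t)
  noise <- if (indicator$noise_sd > 0) {
    draw <- function() rnorm(length(t), 0, indicator$noise_sd)
    if (is.null(seed)) draw() else with_seed(seed, draw())
  } else rep(0, length(t))
  truth <- trace_truth(stim, kernel, indicator, roi)
  out <- tibble::tibble(roi = roi, time = t, value = baseline + sig + noise)
  attr(out, "truth") <- truth
  out
}

# Ground-truth half-max statistics from a dense noiseless steady-state
# cycle (global-maximum peak; for DUAL this is the dominant OFF-phase
# peak). Deliberately avoids the prominence machinery of the kinetics
# module so it can serve as an independent oracle.
trace_truth <- function(stim, kernel, indicator, roi, rate_dense = 20) {
  if (kernel$label == "NONRESPONSIVE") {
    return(tibble::tibble(roi = roi, label = kernel$label,
                          lux_half_max = NA_real_, width_half = NA_real_))
  }
  period <- 2 * stim$ramp_s
  dense <- indicator_spec(indicator$tau_rise, indicator$tau_decay,
                          noise_sd = 0, rate_hz = rate_dense)
  dt <- 1 / rate_dense
  warm <- ramp_stimulus(stim$min_lux, stim$max_lux, stim$ramp_s,
                        n_cycles = max(stim$n_cycles, 4), t_start = 0)
  t <- seq(0, stim_duration(warm) - dt / 2, by = dt)
  sig <- noiseless_signal(warm, kernel, dense, t)
  last <- t >= stim_duration(warm) - period - dt / 2
  z <- sig[last]
  tc <- cycle_fold(warm, t[last])
  ord <- order(tc)
  z <- z[ord]
  tc <- tc[ord]
  n <- length(z)
  p <- which.max(z)
  level <- min(z) + (max(z) - min(z)) / 2
  step_to_level <- function(step) {
    i <- p
    for (s in seq_len(n)) {
      j <- ((i - 1L + step) %% n) + 1L
      if (z[j] <= level) {
        frac <- (z[i] - level) / (z[i] - z[j])
        return(step * ((s - 1) + frac) * dt)
      }
      i <- j
    }
    step * n * dt
  }
  t_left <- tc[p] + step_to_level(-1L)
  t_right <- tc[p] + step_to_level(1L)
  tibble::tibble(
    roi = roi, label = kernel$label,
    lux_half_max = lux_at_tau(stim, t_left %% period),
    width_half = t_right - t_left
  )
}

#' Simulate a balanced labelled trace dataset
#'
#' Generates `n_per_class` traces for each of the four response labels
#' with per-unit parameter jitter (tuning centre, width and amplitude),
#' reproducibly under `seed`.
#'
#' @param stim a [ramp_stimulus()].
#' @param n_per_class traces per label.
#' @param indicator an [indicator_spec()]; its `noise_sd` applies to
#'   every trace.
#' @param labels which labels to include.
#' @param jitter fractional jitter: tuning centres move by a Gaussian
#'   of sd `jitter * (max_lux - min_lux) / 4`, widths and amplitudes by
#'   a factor `exp(N(0, jitter))`.
#' @param seed integer seed; the same seed reproduces the dataset
#'   exactly.
#' @return A list with elements `traces` (long tibble `roi`, `time`,
#'   `value`) and `truth` (tibble `roi`, `label`, kernel parameters,
#'   `lux_half_max`, `width_half`).
#' @export
simulate_dataset <- function(stim, n_per_class = 25,
                             indicator = indicator_spec(),
                             labels = c("ON", "OFF", "DUAL", "NONRESPONSIVE"),
                             jitter = 0.1, seed = 1) {
  lux_range <- stim$max_lux - stim$min_lux
  params <- with_seed(seed, {
    purrr::map(labels, function(lb) {
      base <- response_kernel(lb)
      tibble::tibble(
        label = lb,
        center_lux = if (lb == "NONRESPONSIVE") NA_real_ else
          pmin(stim$max_lux, pmax(stim$min_lux,
            base$center_lux + rnorm(n_per_class, 0, jitter * lux_range / 4))),
        width_lux = base$width_lux * exp(rnorm(n_per_class, 0, jitter)),
        amplitude = base$amplitude * exp(rnorm(n_per_class, 0, jitter)),
        dual_ratio = base$dual_ratio,
        noise_seed = sample.int(.Machine$integer.max, n_per_class)
      )
    }) |> purrr::list_rbind()
  })
  params$roi <- sprintf("roi%03d", seq_len(nrow(params)))
  pieces <- purrr::pmap(params, function(label, center_lux, width_lux,
                                         amplitude, dual_ratio, noise_seed,
                                         roi) {
    kern <- if (label == "NONRESPONSIVE") response_kernel("NONRESPONSIVE")
      else response_kernel(label, center_lux, width_lux, amplitude, dual_ratio)
    simulate_trace(stim, kern, indicator, roi = roi, seed = noise_seed)
  })
  truth <- purrr::map(pieces, attr, "truth") |> purrr::list_rbind()
  truth <- dplyr::left_join(
    truth,
    dplyr::select(params, "roi", "center_lux", "width_lux", "amplitude"),
    by = "roi")
  list(traces = purrr::list_rbind(pieces), truth = truth)
}
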
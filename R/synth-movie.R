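# Synthetic calcium movies with known active regions, the ground-truth
# fixture for activity-threshold segmentation.

#' Simulate a calcium movie with known active regions
#'
#' Builds a `H x W x T` stack in which pixels inside each active region
#' share that region's noiseless response trace (a [response_kernel()]
#' played along the ramp and convolved with the indicator), scaled by
#' `amplitude`, on top of a constant baseline; every pixel receives
#' independent Gaussian noise of sd `amplitude / snr`. Region masks
#' must not overlap.
#'
#' @param stim a [ramp_stimulus()]; the movie spans the full stimulus
#'   (at least two cycles recommended).
#' @param regions list of regions, each a list with elements `mask`
#'   (logical `H x W` matrix) and `kernel` (a [response_kernel()]).
#'   Use [place_square_regions()] to build one.
#' @param dim_hw frame size `c(H, W)`; must match the masks.
#' @param indicator an [indicator_spec()]; its `noise_sd` is ignored in
#'   favour of `amplitude / snr`.
#' @param baseline background intensity.
#' @param amplitude peak signal added inside active regions.
#' @param snr amplitude-to-noise-sd ratio.
#' @param seed integer seed.
#' @return A list: `movie` (array `H x W x T`), `truth_mask` (logical
#'   `H x W`, union of region masks), `time`, `regions`.
#' @export
simulate_movie <- function(stim = ramp_stimulus(ramp_s = 30, n_cycles = 2),
                           regions, dim_hw = c(64, 64),
                           indicator = indicator_spec(rate_hz = 1),
                           baseline = 70, amplitude = 100, snr = 5,
                           seed = 1) {
  h <- dim_hw[1]; w <- dim_hw[2]
  truth <- matrix(FALSE, h, w)
  for (rg in regions) {
    if (!all(dim(rg$mask) == c(h, w))) abort("region mask shape mismatch")
    if (any(truth & rg$mask)) abort("active region masks must not overlap")
    truth <- truth | rg$mask
  }
  dt <- 1 / indicator$rate_hz
  t <- seq(stim$t_start, stim$t_start + stim_duration(stim) - dt / 2, by = dt)
  T_ <- length(t)
  noise_sd <- amplitude / snr
  movie <- with_seed(seed, {
    m <- array(rnorm(h * w * T_, baseline, noise_sd), dim = c(h, w, T_))
    for (rg in regions) {
      sig <- amplitude * noiseless_signal(stim, rg$kernel, indicator, t)
      px <- which(rg$mask)
      for (k in seq_len(T_)) {
        frame <- m[, , k]
        frame[px] <- frame[px] + sig[k]
        m[, , k] <- frame
      }
    }
    m
  })
  list(movie = movie, truth_mask = truth, time = t, regions = regions)
}

#' Place non-touching square active regions in a frame
#'
#' Samples `n` axis-aligned `size x size` squares, separated by at
#' least `margin` pixels so distinct regions never share an
#' 8-neighbourhood, each tied to a response kernel.
#'
#' @param n number of regions.
#' @param size square side in pixels.
#' @param dim_hw frame size `c(H, W)`.
#' @param kernels list of [response_kernel()]s recycled across regions.
#' @param margin minimum pixel separation between regions.
#' @param seed integer seed.
#' @return A list of regions suitable for [simulate_movie()].
#' @export
place_square_regions <- function(n, size = 10, dim_hw = c(64, 64),
                                 kernels = list(response_kernel("OFF", width_lux = 4)),
                                 margin = 2, seed = 1) {
  h <- dim_hw[1]; w <- dim_hw[2]
  if (size > min(h, w)) abort("region larger than frame")
  with_seed(seed, {
    placed <- list()
    occupied <- matrix(FALSE, h, w)
    tries <- 0
    while (length(placed) < n) {
      tries <- tries + 1
      if (tries > 1000) abort("could not place non-overlapping regions")
      r0 <- sample.int(h - size + 1, 1)
      c0 <- sample.int(w - size + 1, 1)
      rr <- max(1, r0 - margin):min(h, r0 + size - 1 + margin)
      cc <- max(1, c0 - margin):min(w, c0 + size - 1 + margin)
      if (any(occupied[rr, cc])) next
      mask <- matrix(FALSE, h, w)
      mask[r0:(r0 + size - 1), c0:(c0 + size - 1)] <- TRUE
      occupied[rr, cc] <- TRUE
      placed[[length(placed) + 1]] <- list(
        mask = mask,
        kernel = kernels[[(length(placed) %% length(kernels)) + 1]]
      )
    }
    placed
  })
}
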
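test_that("simple peaks are detected with the expected prominences", {
  # single triangular bump of height 2 over baseline 0
  z <- c(0, 0, 1, 2, 1, 0, 0, 0)
  pk <- find_cycle_peaks(cycle_tbl(z))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$prominence, 2)
  expect_equal(pk$t_peak, 3)
  # two bumps of heights 2 and 1 separated by a saddle at 0
  z2 <- c(0, 2, 0, 1, 0, 0)
  pk2 <- find_cycle_peaks(cycle_tbl(z2))
  expect_equal(sort(pk2$prominence), c(1, 2))
  # a bump of prominence 0.5 is not significant at the 0.75 threshold
  expect_equal(nrow(find_cycle_peaks(cycle_tbl(c(0, 0.5, 0, 0)))), 0)
  # prominence exactly at the threshold is not "greater than"
  expect_equal(nrow(find_cycle_peaks(cycle_tbl(c(0, 0.75, 0, 0)))), 0)
  expect_equal(nrow(find_cycle_peaks(cycle_tbl(c(0, 0.76, 0, 0)))), 1)
})

test_that("peaks straddling the cycle seam are found exactly once", {
  z <- c(2, 1, 0, 0, 0, 1)  # peak at the seam (index 1)
  pk <- find_cycle_peaks(cycle_tbl(z))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$t_peak, 0)
  expect_equal(pk$prominence, 2)
})

test_that("peak detection matches the brute-force prominence oracle exhaustively", {
  vals <- 0:2
  for (len in 3:7) {
    grid <- as.matrix(expand.grid(rep(list(vals), len)))
    for (i in seq_len(nrow(grid))) {
      z <- as.numeric(grid[i, ])
      got <- find_cycle_peaks(cycle_tbl(z), min_prominence = 0)
      want <- oracle_peaks(z)
      expect_equal(nrow(got), nrow(want),
                   info = paste("signal:", paste(z, collapse = ",")))
      expect_equal(sort(got$prominence), sort(want$prominence),
                   info = paste("signal:", paste(z, collapse = ",")))
    }
  }
  # random longer signals on a finer value grid
  set.seed(4)
  for (i in 1:300) {
    z <- sample(seq(0, 3, by = 0.5), 12, replace = TRUE)
    got <- find_cycle_peaks(cycle_tbl(z), min_prominence = 0)
    want <- oracle_peaks(z)
    expect_equal(sort(got$prominence), sort(want$prominence),
                 info = paste("signal:", paste(z, collapse = ",")))
  }
})

test_that("half-max widths use interpolated crossings and average across peaks", {
  # symmetric triangular bump with 8 s base -> width 4 s at half height
  z <- c(0, 0, 0.5, 1, 1.5, 2, 1.5, 1, 0.5, 0, 0, 0)
  pk <- find_cycle_peaks(cycle_tbl(z))
  expect_equal(pk$width, 4)
  expect_equal(pk$left_half_t, 3)
  expect_equal(pk$right_half_t, 7)
  # two significant peaks with widths 4 and 6 -> mean 5
  tri <- function(center, half_base, h, n) {
    t <- seq_len(n) - 1
    pmax(0, h * (1 - abs(t - center) / half_base))
  }
  z2 <- tri(6, 4, 2, 30) + tri(20, 6, 2, 30)
  w <- width_at_half_max(find_cycle_peaks(cycle_tbl(z2)))
  expect_equal(w$width_at_half_max, 5)
  expect_equal(w$n_peaks, 2L)
})

test_that("LUX at half-max maps the rising crossing of the dominant peak", {
  stim <- ramp_stimulus(ramp_s = 10, n_cycles = 1)
  # dominant peak on the falling leg at t = 15; the interpolated rising
  # half-max crossing lands at t = 13.5 and maps through the falling ramp
  z <- c(rep(0, 13), 1, 2, 3, 2, 1, rep(0, 2))
  res <- lux_at_half_max(find_cycle_peaks(cycle_tbl(z, dt = 1)), stim)
  expect_equal(res$t_half, 13.5)
  expect_equal(res$lux_at_half_max, lux_at(stim, 13.5)$lux)
  expect_equal(res$phase, "FALLING")
  expect_true(res$lux_at_half_max >= 0.4 && res$lux_at_half_max <= 32)
})

test_that("noiseless synthetic traces recover their ground-truth kinetics", {
  ind <- indicator_spec(noise_sd = 0, rate_hz = 10)
  for (lab in c("OFF", "ON", "DUAL")) {
    stim <- ramp_stimulus(n_cycles = 4)
    tr <- simulate_trace(stim, response_kernel(lab), ind, roi = lab)
    truth <- attr(tr, "truth")
    cyc <- cycle_average(zscore_traces(tr, stim), stim, rate_hz = 10)
    kin <- kinetics_summary(cyc, stim)
    # one-sample interpolation tolerance: dt = 0.1 s -> 0.32 LUX
    expect_equal(kin$lux_at_half_max, truth$lux_half_max, tolerance = 0.4,
                 ignore_attr = TRUE)
    if (lab == "DUAL") expect_equal(kin$class_hint, "dual-peak")
  }
  # an OFF peak sits at the cycle seam: symmetric flanks, crossing on
  # the falling leg maps inside the luminance range
  stim <- ramp_stimulus(n_cycles = 4)
  tr <- simulate_trace(stim, response_kernel("OFF"), ind, roi = "off")
  cyc <- cycle_average(zscore_traces(tr, stim), stim, rate_hz = 10)
  pk <- find_cycle_peaks(cyc)
  expect_equal(nrow(pk), 1)
  expect_true(pk$t_peak > 15 || pk$t_peak < 5)  # near the seam
})

test_that("width scales with ramp duration for luminance-domain kernels", {
  # fast indicator so the response tracks the firing rate
  ind <- indicator_spec(tau_rise = 0.01, tau_decay = 0.05, noise_sd = 0,
                        rate_hz = 20)
  kern <- response_kernel("ON", width_lux = 6)
  widths <- sapply(c(10, 30), function(rs) {
    stim <- ramp_stimulus(ramp_s = rs, n_cycles = 2)
    tr <- simulate_trace(stim, kern, ind, roi = "u")
    cyc <- cycle_average(zscore_traces(tr, stim), stim, rate_hz = 20)
    width_at_half_max(find_cycle_peaks(cyc))$width_at_half_max
  })
  expect_equal(widths[2] / widths[1], 3, tolerance = 0.05)
})

test_that("undefined kinetics are reported when no peak is significant", {
  cyc <- cycle_tbl(c(0, 0.1, 0, 0.05, 0, 0))
  stim <- ramp_stimulus(ramp_s = 3, n_cycles = 1)
  kin <- kinetics_summary(cyc, stim)
  expect_equal(kin$n_peaks, 0L)
  expect_true(is.na(kin$lux_at_half_max))
  expect_equal(kin$class_hint, "no-peak")
})

test_that("kinetics are invariant to circular rotation with matching phase shift", {
  z <- c(0, 0, 1, 2.5, 1, 0, 0, 0.3, 0, 0)
  base <- find_cycle_peaks(cycle_tbl(z))
  for (shift in c(2, 5, 7)) {
    rot <- c(z[-seq_len(shift)], z[seq_len(shift)])
    pk <- find_cycle_peaks(cycle_tbl(rot))
    expect_equal(sort(pk$prominence), sort(base$prominence))
    expect_equal(pk$width, base$width)
  }
})
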
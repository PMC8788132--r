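# Small deterministic movie: H x W x T array from a list of traces.
movie_from_traces <- function(traces, h, w) {
  T_ <- length(traces[[1]])
  m <- array(0, dim = c(h, w, T_))
  k <- 1
  for (j in seq_len(w)) for (i in seq_len(h)) {
    m[i, j, ] <- traces[[k]]
    k <- k + 1
  }
  m
}

test_that("the 175% threshold is exact at the boundary", {
  # pixel mean 10: max 17 stays inactive, 18 becomes active (17.5 cut)
  tr_inactive <- c(rep(83 / 9, 9), 17)          # mean 10, max 17
  tr_active <- c(rep(9.11111111111111, 9), 18)  # mean 10, max 18
  tr_exact <- c(rep(9.166666666666666, 9), 17.5)
  m <- movie_from_traces(list(tr_inactive, tr_active, tr_exact,
                              rep(5, 10)), 2, 2)
  mask <- active_pixel_mask(m)
  expect_false(mask[1, 1])
  expect_true(mask[2, 1])
  expect_true(mask[1, 2])   # >= is inclusive at exactly 1.75 x mean
  expect_false(mask[2, 2])  # constant pixel
})

test_that("constant movies give an empty mask and zero-mean pixels warn", {
  m <- array(3, dim = c(4, 4, 6))
  expect_equal(sum(active_pixel_mask(m)), 0)
  m[1, 1, ] <- 0
  expect_warning(mask <- active_pixel_mask(m), "excluded")
  expect_false(mask[1, 1])
})

test_that("the active mask is invariant to positive gain", {
  regs <- place_square_regions(2, size = 8, seed = 3)
  mv <- simulate_movie(regions = regs, seed = 3)
  m1 <- active_pixel_mask(mv$movie, smooth_window = 3)
  m2 <- active_pixel_mask(mv$movie * 7.3, smooth_window = 3)
  expect_identical(m1, m2)
})

test_that("ROI grouping separates disjoint regions and filters small ones", {
  regs <- place_square_regions(2, size = 8, seed = 2)
  mv <- simulate_movie(regions = regs, snr = 50, seed = 2)
  mask <- active_pixel_mask(mv$movie, smooth_window = 3)
  rois <- group_rois(mv$movie, mask)
  expect_equal(nrow(rois$rois), 2)
  # areas are conserved between the label image and the table
  expect_equal(sum(rois$rois$n_px), sum(rois$labels > 0))
  # a lone region smaller than min_size_px disappears
  small <- matrix(FALSE, 8, 8); small[4, 4:5] <- TRUE
  tr <- array(1, dim = c(8, 8, 10))
  tr[4, 4, 5] <- 5; tr[4, 5, 5] <- 5
  rois2 <- group_rois(tr, small, min_size_px = 4)
  expect_equal(nrow(rois2$rois), 0)
})

test_that("adjacent anticorrelated regions split into two ROIs", {
  set.seed(8)
  h <- 6; w <- 8; T_ <- 40
  bump <- rep(0, T_); bump[10:15] <- 1
  m <- array(rnorm(h * w * T_, 0, 0.01), dim = c(h, w, T_))
  for (t in seq_len(T_)) {
    m[, 1:4, t] <- m[, 1:4, t] + 1 + bump[t]       # region A
    m[, 5:8, t] <- m[, 5:8, t] + 2 - bump[t]       # region B, anticorrelated
  }
  mask <- matrix(TRUE, h, w)
  rois <- group_rois(m, mask, corr_min = 0.7, smooth_window = 1)
  expect_equal(nrow(rois$rois), 2)
  sides <- sort(sapply(seq_len(nrow(rois$rois)), function(i)
    mean(which(rois$labels == i, arr.ind = TRUE)[, 2])))
  expect_lt(sides[1], 4.6)
  expect_gt(sides[2], 4.4)
})

test_that("active-area fraction follows ROI and reference areas", {
  labels <- matrix(0L, 10, 10)
  labels[1:5, 1:4] <- 1L
  rois <- structure(list(labels = labels), class = "roi_set")
  total <- matrix(TRUE, 10, 10)
  expect_equal(active_area_fraction(rois, total), 0.2)
  expect_equal(active_area_fraction(rois, labels > 0), 1.0)
  rois0 <- structure(list(labels = labels * 0L), class = "roi_set")
  expect_equal(active_area_fraction(rois0, total), 0)
  expect_error(active_area_fraction(rois, total & FALSE), "empty")
})

test_that("layer tallies use centroids with a majority fallback", {
  labels <- matrix(0L, 10, 10)
  labels[2:4, 2:4] <- 1L            # fully inside layer 1
  labels[7:9, 4:8] <- 2L            # straddles layers 60/40
  rois <- structure(list(
    labels = labels,
    rois = tibble::tibble(roi = 1:2, n_px = c(9L, 15L),
                          centroid_row = c(3, 8), centroid_col = c(3, 6))),
    class = "roi_set")
  layer <- matrix(0L, 10, 10)
  layer[, 1:6] <- 1L
  layer[, 7:10] <- 2L
  tally <- layer_tally(rois, layer, layer_names = c("SFGS5/6", "SGC"))
  expect_equal(tally$n_rois[tally$layer == "SFGS5/6"], 2L)
  # an ROI outside every layer lands in "unassigned"
  layer0 <- matrix(0L, 10, 10)
  t2 <- layer_tally(rois, layer0)
  expect_equal(t2$layer, "unassigned")
  expect_equal(t2$n_rois, 2L)
})

test_that("synthetic movies are recovered: exact count, covered truth, area within 15%", {
  regs <- place_square_regions(3, size = 10, seed = 6)
  mv <- simulate_movie(regions = regs, seed = 6)
  mask <- active_pixel_mask(mv$movie, smooth_window = 3)
  # the mask covers (nearly all of) the ground truth with few false positives
  expect_gte(mean(mask[mv$truth_mask]), 0.95)
  expect_lt(mean(mask[!mv$truth_mask]), 0.05)
  rois <- group_rois(mv$movie, mask)
  expect_equal(nrow(rois$rois), 3)
  area <- sum(rois$labels > 0)
  expect_lt(abs(area - 300) / 300, 0.15)
  frac <- active_area_fraction(rois, matrix(TRUE, 64, 64))
  expect_equal(frac, area / 4096)
})
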
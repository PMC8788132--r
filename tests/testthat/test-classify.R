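stim5 <- ramp_stimulus(n_cycles = 5)

test_that("featurisation is the identity at matching length and preserves constants", {
  z <- c(0, 1, 2, 1, 0, -1, -2, -1)
  feats <- featurize(cycle_tbl(z), L = 8)
  expect_equal(as.numeric(feats[1, -1]), z)
  const <- featurize(cycle_tbl(rep(0.3, 8)), L = 20)
  expect_equal(as.numeric(const[1, -1]), rep(0.3, 20))
  # round-trip error vanishes as L grows
  smooth <- sin(seq(0, 2 * pi, length.out = 33)[1:32])
  err <- sapply(c(8, 16, 32), function(L) {
    down <- featurize(cycle_tbl(smooth), L = L)
    up <- featurize(cycle_tbl(as.numeric(down[1, -1]), dt = 32 / L), L = 32)
    max(abs(as.numeric(up[1, -1]) - smooth))
  })
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-9)
})

test_that("noiseless classes are perfectly separable and predictions honour the gate", {
  ds <- small_dataset(n = 6, noise_sd = 0)
  cyc <- cycle_average(zscore_traces(ds$traces, stim5), stim5)
  feats <- featurize(cyc)
  fit <- train_response_svm(feats, ds$truth, folds = 5, seed = 1)
  expect_equal(fit$mean_accuracy, 1.0)
  expect_equal(sum(diag(fit$confusion)), 24)
  # training items predict their own labels
  pred <- predict_response_class(fit, feats)
  expect_equal(pred$label,
               ds$truth$label[match(pred$roi, ds$truth$roi)])
  # a gated-out ROI is NONRESPONSIVE regardless of the model
  gate <- tibble::tibble(roi = feats$roi,
                         responsive = feats$roi != feats$roi[1])
  pred2 <- predict_response_class(fit, feats, gate = gate)
  expect_equal(pred2$label[1], "NONRESPONSIVE")
})

test_that("shuffled labels give chance-level accuracy", {
  ds <- small_dataset(n = 10, noise_sd = 0.2)
  cyc <- cycle_average(zscore_traces(ds$traces, stim5), stim5)
  feats <- featurize(cyc)
  sh <- with_seed(123, sample(ds$truth$label))
  fit <- train_response_svm(feats, sh, folds = 5, seed = 1)
  expect_lt(fit$mean_accuracy, 0.45)  # 4 balanced classes, chance 0.25
  # a class with fewer examples than folds cannot be stratified
  expect_error(train_response_svm(feats[1:12, ], ds$truth, folds = 5),
               "at least")
  expect_error(train_response_svm(feats[1:8, ], ds$truth, folds = 5),
               "classes")
})

test_that("accuracy degrades with noise on average (parameter recovery)", {
  accs <- sapply(c(0.1, 0.6, 2), function(ns) {
    mean(sapply(1:2, function(s) {
      ds <- small_dataset(n = 8, noise_sd = ns, seed = 100 + s)
      cyc <- cycle_average(zscore_traces(ds$traces, stim5), stim5)
      train_response_svm(featurize(cyc), ds$truth, seed = 1)$mean_accuracy
    }))
  })
  expect_true(accs[1] >= accs[2] && accs[2] >= accs[3])
})

test_that("k-means selects the right cluster number and bins clusters to classes", {
  ds <- small_dataset(n = 12, noise_sd = 0.15, seed = 21)
  cyc <- cycle_average(zscore_traces(ds$traces, stim5), stim5)
  feats <- featurize(cyc)
  km <- cluster_responses(feats, stim5, replicates = 25, seed = 3)
  expect_gte(km$k_opt, 3)
  agree <- dplyr::left_join(km$assignment, ds$truth, by = "roi")
  expect_gte(mean(agree$label.x == agree$label.y), 0.95)
  # deterministic under the seed
  km2 <- cluster_responses(feats, stim5, replicates = 25, seed = 3)
  expect_identical(km$assignment, km2$assignment)
  expect_identical(tidy(km), km$criterion)
})

test_that("a single blob clusters to the minimum k with one bin", {
  set.seed(6)
  n <- 40
  feats <- tibble::as_tibble(matrix(rnorm(n * 10, 0, 0.05), n, 10),
                             .name_repair = ~ paste0("f", 1:10))
  feats$roi <- sprintf("r%02d", 1:n)
  stim <- ramp_stimulus(ramp_s = 5)
  km <- cluster_responses(feats, stim, max_k = 6, replicates = 25, seed = 1)
  expect_lte(km$k_opt, 2)
  expect_equal(unique(km$binning$label), "NONRESPONSIVE")
})

test_that("class proportions reproduce printed-count arithmetic", {
  labels <- tibble::tibble(label = rep(c("ON", "OFF", "DUAL"), c(10, 49, 2)))
  props <- class_proportions(labels)
  expect_equal(props$percent[props$label == "OFF"], 100 * 49 / 61)
  expect_equal(round(props$percent[props$label == "OFF"], 1), 80.3)
  expect_equal(round(props$percent[props$label == "ON"], 1), 16.4)
  expect_equal(round(props$percent[props$label == "DUAL"], 1), 3.3)
  expect_equal(sum(props$fraction), 1)
  # nonresponsive rows are excluded from the denominator
  labels2 <- dplyr::bind_rows(labels,
                              tibble::tibble(label = rep("NONRESPONSIVE", 39)))
  expect_equal(class_proportions(labels2)$fraction, props$fraction)
  # all one class
  expect_equal(class_proportions(tibble::tibble(label = rep("ON", 5)))$fraction, 1)
  # per-animal SEM
  labels3 <- tibble::tibble(label = rep(c("ON", "OFF"), 10),
                            animal = rep(1:2, each = 10))
  expect_equal(class_proportions(labels3)$sem, c(0, 0))
})
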
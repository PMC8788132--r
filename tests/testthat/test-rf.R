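test_that("rf maps place responses at the presented position only", {
  cb <- checkerboard_stimulus(seed = 2)
  sched <- trial_schedule(cb)
  # a unit responding only when position (2, 3) is shown, noise free
  target <- sched[sched$row == 2 & sched$col == 3, ]
  t <- seq(0, 480, by = 1)
  v <- rep(0, length(t))
  v[t >= target$t_on & t <= target$t_on + 3] <- 1
  resp <- tibble::tibble(unit = "u1", side = "contra", time = t, value = v)
  map <- rf_map(resp, list(contra = sched))
  hot <- map[map$z >= 1.5, ]
  expect_equal(nrow(hot), 1)
  expect_equal(c(hot$row, hot$col), c(2, 3))
  # a flat trace yields an all-zero map
  flat <- dplyr::mutate(resp, value = 0)
  expect_true(all(rf_map(flat, list(contra = sched))$z == 0))
  # missing trials error
  expect_error(rf_map(resp[resp$time < 100, ], list(contra = sched)),
               "trial")
})

test_that("rf maps are equivariant to the presentation order", {
  scene <- simulate_rf_scene(n_rgc = 4, n_smtl = 2, n_pyrn = 1, seed = 11)
  mk <- function(seed_c, seed_i) {
    rr <- simulate_rf_responses(
      scene,
      stim_contra = checkerboard_stimulus(side = "left", seed = seed_c),
      stim_ipsi = checkerboard_stimulus(side = "right", seed = seed_i),
      indicator = indicator_spec(rate_hz = 1, noise_sd = 1e-9), seed = 1)
    rf_map(rr$responses, rr$schedules) |>
      dplyr::arrange(unit, side, row, col) |>
      dplyr::mutate(hot = z >= 1.5)
  }
  m1 <- mk(101, 102)
  m2 <- mk(201, 202)
  expect_equal(m1$hot, m2$hot)
})

test_that("rf size counts the z >= 1.5 positions inclusively and monotonically", {
  map <- tibble::tibble(unit = "u", side = "contra", trial = 1:4,
                        row = 1, col = 1:4, z = c(2.0, 1.5, 1.49, 0.3))
  expect_equal(rf_size(map)$size, 2)
  expect_equal(rf_size(dplyr::mutate(map, z = 0))$size, 0)
  zs <- seq(0, 3, by = 0.5)
  sizes <- sapply(zs, function(zm) rf_size(map, z_min = zm)$size)
  expect_true(all(diff(sizes) <= 0))
})

test_that("binocular summaries compute sizes, ratios and component counts", {
  grid_map <- function(unit, side, hot) {
    tibble::tibble(unit = unit, side = side,
                   trial = 1:24,
                   row = rep(1:4, each = 6), col = rep(1:6, 4),
                   z = ifelse(hot, 3, 0))
  }
  hot_contra <- rep(FALSE, 24); hot_contra[1:8] <- TRUE     # 8 positions
  hot_ipsi <- rep(FALSE, 24); hot_ipsi[13:16] <- TRUE       # 4 positions
  map <- dplyr::bind_rows(grid_map("u1", "contra", hot_contra),
                          grid_map("u1", "ipsi", hot_ipsi))
  s <- binocular_summary(map)
  expect_equal(s$ratio, 2.0)
  expect_true(s$binocular)
  expect_equal(s$size_total, 12)
  # monocular: ratio undefined
  map2 <- dplyr::bind_rows(grid_map("u2", "contra", hot_contra),
                           grid_map("u2", "ipsi", rep(FALSE, 24)))
  s2 <- binocular_summary(map2)
  expect_false(s2$binocular)
  expect_true(is.na(s2$ratio))
  # two separated hot blocks -> two 8-connected components
  hot2 <- rep(FALSE, 24); hot2[c(1, 18)] <- TRUE
  s3 <- binocular_summary(dplyr::bind_rows(
    grid_map("u3", "contra", hot2), grid_map("u3", "ipsi", hot_ipsi)))
  expect_equal(s3$n_components_contra, 2)
})

test_that("noiseless scenes recover footprints exactly and unions dominate sources", {
  scene <- simulate_rf_scene(seed = 7)
  rr <- simulate_rf_responses(scene,
                              indicator = indicator_spec(rate_hz = 1,
                                                         noise_sd = 1e-9),
                              seed = 2)
  map <- rf_map(rr$responses, rr$schedules)
  sz <- rf_size(map) |>
    dplyr::group_by(tier, unit) |>
    dplyr::summarise(size = sum(size), .groups = "drop")
  truth <- purrr::pmap_dfr(scene$units, function(tier, unit, sources, footprint)
    tibble::tibble(unit = unit,
                   truth = sum(footprint$contra) + sum(footprint$ipsi)))
  cmp <- dplyr::left_join(sz, truth, by = "unit")
  expect_equal(cmp$size, cmp$truth)
  # single-position RGC and 3-RGC union sanity
  one <- simulate_rf_scene(n_rgc = 3, n_smtl = 1, n_pyrn = 1,
                           rgc_patch = 1, seed = 13)
  rr1 <- simulate_rf_responses(one, indicator = indicator_spec(
    rate_hz = 1, noise_sd = 1e-9), seed = 3)
  sz1 <- rf_size(rf_map(rr1$responses, rr1$schedules)) |>
    dplyr::group_by(tier, unit) |>
    dplyr::summarise(size = sum(size), .groups = "drop")
  expect_true(all(sz1$size[sz1$tier == "RGC"] == 1))
  fp <- one$units$footprint[[which(one$units$tier == "SMTL")]]
  expect_equal(sz1$size[sz1$tier == "SMTL"], sum(fp$contra) + sum(fp$ipsi))
})

test_that("tier comparison reports means and the convergence ordering flag", {
  mk <- function(tier, sizes) tibble::tibble(tier = tier, size_total = sizes)
  s <- dplyr::bind_rows(mk("RGC", 1), mk("SMTL", 3), mk("PyrN", 9))
  tc <- tier_comparison(s)
  expect_true(tc$ordering)
  expect_equal(tidy(tc)$mean_size[tidy(tc)$tier == "PyrN"], 9)
  same <- dplyr::bind_rows(mk("RGC", c(4, 4)), mk("SMTL", c(4, 4)),
                           mk("PyrN", c(4, 4)))
  expect_false(tier_comparison(same)$ordering)
  expect_false(glance(tier_comparison(same))$ordering)
})
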
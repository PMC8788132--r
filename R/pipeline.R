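# Config-driven pipeline entry points. Each run_* function consumes a
# YAML config (path or list), writes its outputs plus the resolved
# config into `out_dir`, and returns its results invisibly. A thin
# command-line wrapper lives in inst/scripts/ramplux.R.

#' Load and resolve a run configuration
#'
#' Reads a YAML config (or accepts a list), fills stage defaults, and
#' validates the stimulus block. Recognised top-level fields:
#' `stimulus` (`type: ramp` with `min_lux`, `max_lux`, `ramp_s`,
#' `n_cycles`, `t_start`, or `type: checkerboard` with the
#' [checkerboard_stimulus()] fields), `seed`, and per-stage blocks
#' `simulate`, `classify`, `segment`, `rf` whose entries override the
#' function defaults documented on each stage.
#'
#' @param config path to a YAML file or a named list.
#' @return A validated config list of class `ramplux_config`.
#' @export
load_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) abort("config must be a YAML file or a list")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (!is.null(cfg$stimulus)) {
    cfg$stimulus$type <- cfg$stimulus$type %||% "ramp"
  }
  structure(cfg, class = c("ramplux_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_stimulus <- function(cfg) {
  s <- cfg$stimulus %||% list(type = "ramp")
  if (identical(s$type, "checkerboard")) {
    checkerboard_stimulus(
      n_cols = s$n_cols %||% 6, n_rows = s$n_rows %||% 4,
      square_deg = s$square_deg %||% 15, present_s = s$present_s %||% 10,
      gap_s = s$gap_s %||% 10, side = s$side %||% "left",
      seed = s$seed %||% cfg$seed, t_start = s$t_start %||% 0)
  } else {
    ramp_stimulus(min_lux = s$min_lux %||% 0.4, max_lux = s$max_lux %||% 32,
                  ramp_s = s$ramp_s %||% 10, n_cycles = s$n_cycles %||% 5,
                  t_start = s$t_start %||% 0)
  }
}

write_resolved_config <- function(cfg, out_dir) {
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.resolved.yaml"))
}

#' Simulate a labelled dataset to disk
#'
#' Generates a balanced labelled trace dataset under the config's
#' stimulus and writes `traces.csv` (wide trace table) and `truth.csv`
#' (ground-truth sidecar) plus the resolved config.
#'
#' @param config YAML path or list; see [load_config()]. The
#'   `simulate` block accepts `n_per_class`, `noise_sd`, `rate_hz`,
#'   `jitter`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the [simulate_dataset()] result.
#' @export
run_simulate <- function(config, out_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stim <- config_stimulus(cfg)
  p <- cfg$simulate %||% list()
  ind <- indicator_spec(noise_sd = p$noise_sd %||% 0.2,
                        rate_hz = p$rate_hz %||% 2)
  ds <- simulate_dataset(stim, n_per_class = p$n_per_class %||% 25,
                         indicator = ind, jitter = p$jitter %||% 0.1,
                         seed = cfg$seed)
  write_trace_table(ds$traces, file.path(out_dir, "traces.csv"))
  readr::write_csv(ds$truth, file.path(out_dir, "truth.csv"))
  write_resolved_config(cfg, out_dir)
  invisible(ds)
}

#' Classify a trace table end to end
#'
#' Runs normalisation, gating, cycle averaging, kinetics, featurisation
#' and classification on a trace table. With a `labels` file (CSV
#' `roi`, `label`) a linear SVM is trained and cross-validated;
#' without one, unsupervised k-means clustering with centroid binning
#' is used. Writes `labels.csv`, `kinetics.csv`, `class_means.csv`
#' (per-class mean cycle response) and, for the SVM path,
#' `confusion.csv` and `cv.csv`.
#'
#' @param config YAML path or list. The `classify` block accepts
#'   `traces` (input CSV path, required), `labels` (optional CSV),
#'   `L`, `folds`, `cost`, `min_prominence`, `gate_bound`, `max_k`,
#'   `replicates`.
#' @param out_dir output directory.
#' @return Invisibly, a list with `labels`, `kinetics`, `fit`.
#' @export
run_classify <- function(config, out_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$classify %||% list()
  if (is.null(p$traces)) abort("config$classify$traces (input CSV) is required")
  stim <- config_stimulus(cfg)
  traces <- read_trace_table(p$traces)
  zt <- zscore_traces(traces, stim)
  gate <- gate_responsiveness(zt, stim, bound = p$gate_bound %||% 0.5)
  cyc <- cycle_average(zt, stim)
  kin <- kinetics_summary(cyc, stim,
                          min_prominence = p$min_prominence %||% 0.75)
  feats <- featurize(cyc, L = p$L %||% 40)

  if (!is.null(p$labels)) {
    lab <- readr::read_csv(p$labels, show_col_types = FALSE)
    fit <- train_response_svm(feats, lab, folds = p$folds %||% 5,
                              cost = p$cost %||% 1, seed = cfg$seed)
    labels <- predict_response_class(fit, feats, gate = gate)
    readr::write_csv(tibble::as_tibble(as.data.frame(fit$confusion)),
                     file.path(out_dir, "confusion.csv"))
    readr::write_csv(tidy(fit), file.path(out_dir, "cv.csv"))
  } else if (!any(gate$responsive)) {
    fit <- NULL
    labels <- tibble::tibble(roi = gate$roi, label = "NONRESPONSIVE")
  } else {
    fit <- cluster_responses(feats, stim,
                             max_k = min(p$max_k %||% 8, nrow(feats) - 1),
                             replicates = p$replicates %||% 1000,
                             seed = cfg$seed)
    labels <- dplyr::select(fit$assignment, "roi", "label") |>
      dplyr::left_join(gate, by = "roi") |>
      dplyr::mutate(label = ifelse(!.data$responsive, "NONRESPONSIVE",
                                   .data$label)) |>
      dplyr::select("roi", "label")
  }
  readr::write_csv(labels, file.path(out_dir, "labels.csv"))
  readr::write_csv(kin, file.path(out_dir, "kinetics.csv"))
  class_means <- cyc |>
    dplyr::left_join(labels, by = "roi") |>
    dplyr::group_by(.data$label, .data$t_cycle) |>
    dplyr::summarise(z = mean(.data$z), .groups = "drop")
  readr::write_csv(class_means, file.path(out_dir, "class_means.csv"))
  write_resolved_config(cfg, out_dir)
  invisible(list(labels = labels, kinetics = kin, fit = fit))
}

#' Segment a calcium movie
#'
#' Thresholds active pixels, groups them into ROIs, and writes the ROI
#' label mask (`rois.tif`), per-ROI table (`rois.csv`), ROI mean
#' traces (`roi_traces.csv`), the active-area fraction
#' (`area_fraction.csv`) and, when a layer mask is supplied, layer
#' tallies (`layer_tally.csv`).
#'
#' @param config YAML path or list. The `segment` block accepts
#'   `movie` (input TIFF, required), `total_mask` (TIFF; default the
#'   whole frame), `layer_mask` (integer TIFF), `layer_names`,
#'   `n_layers`, `threshold_pct`, `smooth_window`, `min_size_px`,
#'   `corr_min`, `min_mean`.
#' @param out_dir output directory.
#' @return Invisibly, a list with `rois`, `fraction`, `tally`.
#' @export
run_segment <- function(config, out_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$segment %||% list()
  if (is.null(p$movie)) abort("config$segment$movie (input TIFF) is required")
  movie <- read_movie(p$movie)
  mask <- active_pixel_mask(movie, threshold_pct = p$threshold_pct %||% 175,
                            smooth_window = p$smooth_window %||% 1,
                            min_mean = p$min_mean %||% 0)
  rois <- group_rois(movie, mask, min_size_px = p$min_size_px %||% 4,
                     corr_min = p$corr_min %||% 0.7)
  total <- if (!is.null(p$total_mask)) read_mask(p$total_mask)
    else matrix(TRUE, dim(movie)[1], dim(movie)[2])
  if (!all(dim(total) == dim(movie)[1:2])) abort("total mask shape mismatch")
  fraction <- active_area_fraction(rois, total)
  write_mask(rois$labels > 0, file.path(out_dir, "rois.tif"))
  readr::write_csv(dplyr::select(rois$rois, -"trace"),
                   file.path(out_dir, "rois.csv"))
  traces <- rois$rois |>
    dplyr::mutate(trace = purrr::map(.data$trace, ~ tibble::tibble(
      frame = seq_along(.x), value = .x))) |>
    tidyr::unnest("trace") |>
    dplyr::select("roi", "frame", "value")
  readr::write_csv(traces, file.path(out_dir, "roi_traces.csv"))
  readr::write_csv(tibble::tibble(active_area_fraction = fraction),
                   file.path(out_dir, "area_fraction.csv"))
  tally <- NULL
  if (!is.null(p$layer_mask)) {
    lm <- read_mask(p$layer_mask, n_levels = p$n_layers %||% 1)
    if (!all(dim(lm) == dim(movie)[1:2])) abort("layer mask shape mismatch")
    tally <- layer_tally(rois, lm, layer_names = p$layer_names)
    readr::write_csv(tally, file.path(out_dir, "layer_tally.csv"))
  }
  write_resolved_config(cfg, out_dir)
  invisible(list(rois = rois, fraction = fraction, tally = tally))
}

#' Map receptive fields from trial tables
#'
#' Builds per-unit RF maps from long trial-response tables, then
#' writes the maps (`rf_maps.csv`), binocular summaries
#' (`rf_summary.csv`) and, when several tiers are present, the tier
#' comparison (`tier_comparison.csv`).
#'
#' @param config YAML path or list. The `rf` block accepts `responses`
#'   (CSV with columns `unit`, `side`, `time`, `value`, optional
#'   `tier`; required), `lag_s`, `z_min`, and a `checkerboard` block
#'   (grid/timing fields plus per-side seeds `seed_contra`,
#'   `seed_ipsi`).
#' @param out_dir output directory.
#' @return Invisibly, a list with `maps`, `summary`, `tiers`.
#' @export
run_rf <- function(config, out_dir) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$rf %||% list()
  if (is.null(p$responses)) abort("config$rf$responses (input CSV) is required")
  responses <- readr::read_csv(p$responses, show_col_types = FALSE)
  cb <- p$checkerboard %||% list()
  mk <- function(side, seed) {
    checkerboard_stimulus(
      n_cols = cb$n_cols %||% 6, n_rows = cb$n_rows %||% 4,
      present_s = cb$present_s %||% 10, gap_s = cb$gap_s %||% 10,
      side = side, seed = seed)
  }
  schedules <- list(
    contra = trial_schedule(mk("left", cb$seed_contra %||% cfg$seed)),
    ipsi = trial_schedule(mk("right", cb$seed_ipsi %||% (cfg$seed + 1))))
  maps <- rf_map(responses, schedules, lag_s = p$lag_s %||% 2)
  summary <- binocular_summary(maps, z_min = p$z_min %||% 1.5)
  readr::write_csv(maps, file.path(out_dir, "rf_maps.csv"))
  readr::write_csv(summary, file.path(out_dir, "rf_summary.csv"))
  tiers <- NULL
  if ("tier" %in% names(summary) && length(unique(summary$tier)) > 1) {
    tiers <- tier_comparison(summary)
    readr::write_csv(tidy(tiers), file.path(out_dir, "tier_comparison.csv"))
  }
  write_resolved_config(cfg, out_dir)
  invisible(list(maps = maps, summary = summary, tiers = tiers))
}
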
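# ON/OFF/DUAL/NONRESPONSIVE classification of cycle responses.

response_levels <- c("ON", "OFF", "DUAL", "NONRESPONSIVE")

#' Feature vectors from cycle responses
#'
#' Resamples each ROI's cycle-averaged z trace onto a fixed length `L`
#' by linear interpolation on the cyclic domain, phase aligned so that
#' index 1 is the cycle start (minimum luminance, rising). The z scale
#' from preprocessing is kept, so response amplitude remains
#' informative.
#'
#' @param cycles tibble from [cycle_average()].
#' @param L number of samples per feature vector.
#' @return A wide tibble: `roi` plus numeric columns `f1..fL`.
#' @export
featurize <- function(cycles, L = 40) {
  if (L < 2) abort("`L` must be at least 2")
  cycles |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$t_cycle)
      n <- nrow(df)
      if (n < 2) abort("degenerate cycle response")
      dt <- df$t_cycle[2] - df$t_cycle[1]
      period <- n * dt
      xout <- seq(0, period, length.out = L + 1)[seq_len(L)]
      y <- resample_linear(c(df$t_cycle, period), c(df$z, df$z[1]), xout)
      tibble::as_tibble(setNames(as.list(y), paste0("f", seq_len(L))))
    }) |>
    dplyr::ungroup()
}

feature_matrix <- function(features) {
  cols <- grepl("^f[0-9]+$", names(features))
  m <- as.matrix(features[, cols])
  rownames(m) <- features$roi
  m
}

#' Train a linear SVM response classifier with cross-validation
#'
#' Fits a linear-kernel multiclass SVM (one-vs-one voting) to labelled
#' feature vectors and estimates performance by stratified k-fold
#' cross-validation: per-fold accuracies, their mean, and the pooled
#' confusion matrix over held-out predictions. The returned model is
#' refit on all data.
#'
#' @param features wide tibble from [featurize()].
#' @param labels tibble `roi`, `label`, or a vector aligned with
#'   `features` rows.
#' @param folds number of cross-validation folds.
#' @param cost SVM cost parameter.
#' @param seed seed for the stratified fold assignment.
#' @return An object of class `svm_cv` with elements `model`,
#'   `fold_accuracies`, `mean_accuracy`, `confusion` (true x
#'   predicted), `levels`, `L`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
train_response_svm <- function(features, labels, folds = 5, cost = 1,
                               seed = 1) {
  m <- feature_matrix(features)
  y <- align_labels(features, labels)
  lev <- intersect(response_levels, unique(y))
  lev <- c(lev, setdiff(unique(y), lev))
  y <- factor(y, levels = lev)
  counts <- table(y)
  if (length(counts) < 2) abort("need at least 2 classes to train")
  if (any(counts < folds)) {
    abort(sprintf("every class needs at least %d examples for %d-fold CV",
                  folds, folds))
  }
  fold <- stratified_folds(as.character(y), folds, seed = seed)
  acc <- numeric(folds)
  confusion <- matrix(0L, length(lev), length(lev),
                      dimnames = list(true = lev, predicted = lev))
  for (f in seq_len(folds)) {
    test <- fold == f
    fit <- e1071::svm(m[!test, , drop = FALSE], y[!test], kernel = "linear",
                      cost = cost, scale = FALSE)
    pred <- predict(fit, m[test, , drop = FALSE])
    acc[f] <- mean(pred == y[test])
    confusion <- confusion + table(factor(y[test], lev), factor(pred, lev))
  }
  model <- e1071::svm(m, y, kernel = "linear", cost = cost, scale = FALSE)
  structure(list(model = model, fold_accuracies = acc,
                 mean_accuracy = mean(acc), confusion = confusion,
                 levels = lev, L = ncol(m), folds = folds, cost = cost,
                 seed = seed),
            class = "svm_cv")
}

align_labels <- function(features, labels) {
  if (is.data.frame(labels)) {
    y <- labels$label[match(features$roi, labels$roi)]
    if (anyNA(y)) abort("labels missing for some ROIs")
    as.character(y)
  } else {
    if (length(labels) != nrow(features)) abort("label length mismatch")
    as.character(labels)
  }
}

#' @export
print.svm_cv <- function(x, ...) {
  cat(sprintf("<svm_cv> linear SVM, %d-fold CV mean accuracy %.3f\n",
              x$folds, x$mean_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Predict response classes
#'
#' Applies a trained [train_response_svm()] model. If a responsiveness
#' gate (from [gate_responsiveness()]) is supplied, ROIs failing the
#' gate are forced to `NONRESPONSIVE` regardless of the model output.
#'
#' @param object an `svm_cv` fit.
#' @param features wide tibble from [featurize()] with the same `L`.
#' @param gate optional tibble `roi`, `responsive`.
#' @return A tibble `roi`, `label`.
#' @export
predict_response_class <- function(object, features, gate = NULL) {
  m <- feature_matrix(features)
  if (ncol(m) != object$L) abort("feature length does not match the model")
  lab <- as.character(predict(object$model, m))
  out <- tibble::tibble(roi = features$roi, label = lab)
  if (!is.null(gate)) {
    out <- out |>
      dplyr::left_join(gate[, c("roi", "responsive")], by = "roi") |>
      dplyr::mutate(label = ifelse(!is.na(.data$responsive) & !.data$responsive,
                                   "NONRESPONSIVE", .data$label)) |>
      dplyr::select("roi", "label")
  }
  out
}

#' Unsupervised clustering of cycle responses
#'
#' Runs k-means for `k = 2..max_k` with `replicates` random restarts
#' each, scores every k with the Calinski-Harabasz criterion, picks
#' the optimal k at the criterion maximum, and bins the resulting
#' clusters into ON/OFF/DUAL/NONRESPONSIVE by the significant-peak
#' profile of each centroid (peak detection as in
#' [find_cycle_peaks()]): no significant peak is nonresponsive, two or
#' more peaks is DUAL, and a single peak is ON or OFF according to the
#' stimulus luminance at the peak (above or below mid-range).
#'
#' @param features wide tibble from [featurize()].
#' @param stim the [ramp_stimulus()] (for centroid peak luminance).
#' @param max_k largest cluster number considered.
#' @param replicates random restarts per k.
#' @param min_prominence significance threshold for centroid peaks.
#' @param seed integer seed.
#' @return An object of class `response_kmeans`: `k_opt`, `criterion`
#'   (tibble `k`, `ch`, `tot_withinss`), `assignment` (tibble `roi`,
#'   `cluster`, `label`), `binning` (tibble `cluster`, `label`),
#'   `centroids`. Supports [tidy()], [glance()], [autoplot()].
#' @export
cluster_responses <- function(features, stim, max_k = 8, replicates = 1000,
                              min_prominence = 0.75, seed = 1) {
  m <- feature_matrix(features)
  n <- nrow(m)
  if (n <= max_k) abort("need more items than `max_k`")
  ks <- 2:max_k
  fits <- with_seed(seed, {
    lapply(ks, function(k) kmeans(m, centers = k, nstart = replicates,
                                  iter.max = 100))
  })
  ch <- vapply(seq_along(ks), function(i) {
    calinski_harabasz(m, fits[[i]])
  }, numeric(1))
  crit <- tibble::tibble(
    k = ks, ch = ch,
    tot_withinss = vapply(fits, function(f) f$tot.withinss, numeric(1)))
  best <- which.max(ch)
  fit <- fits[[best]]
  period <- 2 * stim$ramp_s
  L <- ncol(m)
  tc <- seq(0, period, length.out = L + 1)[seq_len(L)]
  binning <- purrr::map(seq_len(nrow(fit$centers)), function(cl) {
    tibble::tibble(cluster = cl,
                   label = classify_centroid(fit$centers[cl, ], tc, stim,
                                             min_prominence))
  }) |> purrr::list_rbind()
  assignment <- tibble::tibble(roi = rownames(m),
                               cluster = unname(fit$cluster)) |>
    dplyr::left_join(binning, by = "cluster")
  structure(list(k_opt = ks[best], criterion = crit, assignment = assignment,
                 binning = binning, centroids = fit$centers, seed = seed),
            class = "response_kmeans")
}

# Between/within variance ratio criterion for a kmeans fit.
calinski_harabasz <- function(m, fit) {
  n <- nrow(m)
  k <- nrow(fit$centers)
  if (k < 2) return(NA_real_)
  B <- fit$betweenss
  W <- fit$tot.withinss
  if (W <= 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

# Bin one centroid to a response class by its peak profile.
classify_centroid <- function(centroid, t_cycle, stim, min_prominence) {
  pk <- peaks_one_cycle(centroid, t_cycle, min_prominence)
  if (nrow(pk) == 0) return("NONRESPONSIVE")
  if (nrow(pk) >= 2) return("DUAL")
  lux <- lux_at_tau(stim, pk$t_peak %% (2 * stim$ramp_s))
  if (lux >= (stim$min_lux + stim$max_lux) / 2) "ON" else "OFF"
}

#' @export
print.response_kmeans <- function(x, ...) {
  cat(sprintf("<response_kmeans> optimal k = %d (Calinski-Harabasz)\n",
              x$k_opt))
  print(x$binning)
  invisible(x)
}

#' Per-group response class proportions
#'
#' Fraction of each class among responsive items (rows labelled
#' `NONRESPONSIVE` are excluded from the denominator) per group, with
#' a per-animal SEM when an `animal` column is present.
#'
#' @param labels tibble with a `label` column and optional `group` /
#'   `animal` columns.
#' @param by optional grouping column name (default `"group"` when
#'   present).
#' @return A tibble `group` (if any), `label`, `n`, `fraction`,
#'   `percent`, and `sem` (across animals, `NA` without animal ids).
#' @export
class_proportions <- function(labels, by = NULL) {
  if (is.null(by) && "group" %in% names(labels)) by <- "group"
  grouped <- if (is.null(by)) labels else
    dplyr::group_by(labels, dplyr::across(dplyr::all_of(by)))
  resp <- dplyr::filter(grouped, .data$label != "NONRESPONSIVE")
  if (nrow(resp) == 0) abort("no responsive items to summarise")
  counts <- resp |>
    dplyr::count(.data$label, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n),
                  percent = 100 * .data$fraction)
  if ("animal" %in% names(labels)) {
    per_animal <- resp |>
      dplyr::group_by(.data$animal, .add = TRUE) |>
      dplyr::count(.data$label, name = "n") |>
      dplyr::mutate(frac = .data$n / sum(.data$n)) |>
      dplyr::ungroup()
    keys <- c(by, "label")
    sems <- per_animal |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(sem = sd(.data$frac) / sqrt(dplyr::n()),
                       .groups = "drop")
    counts <- dplyr::left_join(dplyr::ungroup(counts), sems, by = keys)
  } else {
    counts <- dplyr::mutate(dplyr::ungroup(counts), sem = NA_real_)
  }
  dplyr::ungroup(counts)
}
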
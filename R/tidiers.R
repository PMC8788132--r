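# broom-style tidiers for fitted objects.

#' Tidy a cross-validated SVM fit
#'
#' @param x an `svm_cv` object from [train_response_svm()].
#' @param ... unused.
#' @return One row per fold: `fold`, `accuracy`.
#' @method tidy svm_cv
#' @export
tidy.svm_cv <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$fold_accuracies),
                 accuracy = x$fold_accuracies)
}

#' @rdname tidy.svm_cv
#' @return `glance()`: one row with `mean_accuracy`, `folds`, `cost`,
#'   `n_classes`.
#' @method glance svm_cv
#' @export
glance.svm_cv <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy, folds = x$folds,
                 cost = x$cost, n_classes = length(x$levels))
}

#' Tidy a response clustering
#'
#' @param x a `response_kmeans` object from [cluster_responses()].
#' @param ... unused.
#' @return The Calinski-Harabasz criterion curve: `k`, `ch`,
#'   `tot_withinss`.
#' @method tidy response_kmeans
#' @export
tidy.response_kmeans <- function(x, ...) x$criterion

#' @rdname tidy.response_kmeans
#' @return `glance()`: one row with `k_opt` and the criterion value at
#'   the optimum.
#' @method glance response_kmeans
#' @export
glance.response_kmeans <- function(x, ...) {
  tibble::tibble(k_opt = x$k_opt,
                 ch_opt = x$criterion$ch[x$criterion$k == x$k_opt])
}

#' Tidy a tier comparison
#'
#' @param x a `tier_comparison` object from [tier_comparison()].
#' @param ... unused.
#' @return Per-tier statistics: `tier`, `n`, `mean_size`, `sem`.
#' @method tidy tier_comparison
#' @export
tidy.tier_comparison <- function(x, ...) x$stats

#' @rdname tidy.tier_comparison
#' @return `glance()`: one row with the `ordering` flag.
#' @method glance tier_comparison
#' @export
glance.tier_comparison <- function(x, ...) {
  tibble::tibble(ordering = x$ordering)
}
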
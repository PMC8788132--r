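# ggplot2 helpers for each result type.

#' Plot per-class mean cycle responses
#'
#' Mean z-scored cycle response per class with a luminance trace
#' underlay, the standard at-a-glance view of how ON, OFF and DUAL
#' classes tile a stimulus cycle.
#'
#' @param cycles tibble from [cycle_average()].
#' @param labels tibble `roi`, `label`.
#' @param stim the [ramp_stimulus()], drawn (rescaled) behind the
#'   responses.
#' @return A ggplot object.
#' @export
plot_class_means <- function(cycles, labels, stim) {
  df <- cycles |>
    dplyr::left_join(labels, by = "roi") |>
    dplyr::group_by(.data$label, .data$t_cycle) |>
    dplyr::summarise(z = mean(.data$z), .groups = "drop")
  lux <- lux_at(stim, stim$t_start + sort(unique(df$t_cycle)))
  lux$z <- with(lux, (lux - min(lux)) / diff(range(lux))) *
    diff(range(df$z)) + min(df$z)
  lux$t_cycle <- sort(unique(df$t_cycle))
  ggplot2::ggplot(df, ggplot2::aes(.data$t_cycle, .data$z)) +
    ggplot2::geom_area(data = lux, fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(colour = .data$label), linewidth = 0.8) +
    ggplot2::labs(x = "time in cycle (s)", y = "mean z-score",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Heatmap of receptive-field maps
#'
#' One tile grid per unit and hemifield, coloured by trial-peak
#' z-score; cells at or above `z_min` are outlined.
#'
#' @param map tibble from [rf_map()].
#' @param z_min threshold drawn as outline.
#' @return A ggplot object.
#' @export
plot_rf_map <- function(map, z_min = 1.5) {
  ggplot2::ggplot(map, ggplot2::aes(.data$col, .data$row, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = ~ dplyr::filter(.x, .data$z >= z_min),
                       fill = NA, colour = "white", linewidth = 0.6) +
    ggplot2::facet_grid(unit ~ side) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "azimuth position", y = "elevation position",
                  fill = "peak z") +
    ggplot2::theme_minimal()
}

#' @method autoplot svm_cv
#' @export
autoplot.svm_cv <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(object$confusion))
  names(df) <- c("true", "predicted", "n")
  df <- df |>
    dplyr::group_by(.data$true) |>
    dplyr::mutate(frac = .data$n / max(sum(.data$n), 1)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$frac)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(object$levels)) +
    ggplot2::scale_x_discrete(limits = object$levels) +
    ggplot2::labs(title = sprintf("5-fold CV accuracy %.1f%%",
                                  100 * object$mean_accuracy),
                  fill = "row fraction") +
    ggplot2::theme_minimal()
}

#' @method autoplot response_kmeans
#' @export
autoplot.response_kmeans <- function(object, ...) {
  ggplot2::ggplot(object$criterion, ggplot2::aes(.data$k, .data$ch)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_opt, linetype = 2) +
    ggplot2::labs(x = "number of clusters k", y = "Calinski-Harabasz index") +
    ggplot2::theme_minimal()
}

#' @method autoplot roi_set
#' @export
autoplot.roi_set <- function(object, ...) {
  df <- tibble::tibble(
    row = as.vector(row(object$labels)),
    col = as.vector(col(object$labels)),
    roi = as.vector(object$labels))
  ggplot2::ggplot(dplyr::filter(df, .data$roi > 0),
                  ggplot2::aes(.data$col, .data$row,
                               fill = factor(.data$roi))) +
    ggplot2::geom_tile(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
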
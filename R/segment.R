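# Activity-threshold segmentation of calcium movies.

#' Active-pixel mask of a calcium movie
#'
#' A pixel is active when its temporal maximum reaches
#' `threshold_pct / 100` times its temporal mean -- the default 175%
#' keeps pixels whose fluorescence changes by at least 75% over that
#' pixel's average intensity. Input movies are assumed
#' background-subtracted; pixels whose temporal mean is not positive
#' (or falls below `min_mean`) cannot be thresholded multiplicatively
#' and are excluded with a warning.
#'
#' `smooth_window > 1` applies a centred moving average over that many
#' frames before taking the maximum, so the detected maximum estimates
#' the transient amplitude rather than the extreme noise excursion;
#' use it for noisy recordings (a window spanning roughly the
#' indicator decay works well). The default (`1`) uses the raw
#' per-frame maximum.
#'
#' With `mode = "dff"` the criterion is instead
#' `(max - F0) / F0 >= threshold_pct / 100 - 1` with `F0` the
#' `f0_quantile` of the pixel's trace, a conventional dF/F reading of
#' the same threshold.
#'
#' @param movie numeric array `H x W x T`.
#' @param threshold_pct detection threshold, percent of the temporal
#'   mean (175 by default).
#' @param smooth_window moving-average width in frames applied before
#'   the temporal maximum; 1 disables smoothing.
#' @param mode `"ratio"` (max over mean, default) or `"dff"`.
#' @param f0_quantile baseline quantile for `mode = "dff"`.
#' @param min_mean exclude pixels with temporal mean below this floor.
#' @return Logical `H x W` matrix.
#' @export
active_pixel_mask <- function(movie, threshold_pct = 175, smooth_window = 1,
                              mode = c("ratio", "dff"), f0_quantile = 0.1,
                              min_mean = 0) {
  mode <- match.arg(mode)
  stopifnot(length(dim(movie)) == 3)
  h <- dim(movie)[1]; w <- dim(movie)[2]
  mu <- apply(movie, c(1, 2), mean)
  sm <- if (smooth_window > 1) smooth_movie(movie, smooth_window) else movie
  mx <- apply(sm, c(1, 2), max)
  valid <- mu > max(0, min_mean)
  if (!all(valid)) {
    warn(sprintf("%d pixel(s) with non-positive or sub-floor mean excluded",
                 sum(!valid)))
  }
  mask <- matrix(FALSE, h, w)
  if (mode == "ratio") {
    mask[valid] <- mx[valid] >= (threshold_pct / 100) * mu[valid]
  } else {
    f0 <- apply(movie, c(1, 2), stats::quantile, probs = f0_quantile,
                names = FALSE)
    ok <- valid & f0 > 0
    mask[ok] <- (mx[ok] - f0[ok]) / f0[ok] >= threshold_pct / 100 - 1
  }
  mask
}

# Centred moving average down the rows of a T x N matrix, with
# shrunken windows at the edges (cumulative-sum trick).
smooth_columns <- function(M, window) {
  T_ <- nrow(M)
  k <- min(window, T_)
  if (k <= 1) return(M)
  half <- (k - 1) %/% 2
  cs <- rbind(0, apply(M, 2, cumsum))
  lo <- pmax(1L, seq_len(T_) - half)
  hi <- pmin(T_, seq_len(T_) + (k - 1L - half))
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

# Centred moving average along the time axis.
smooth_movie <- function(movie, window) {
  d <- dim(movie)
  flat <- matrix(aperm(movie, c(3, 1, 2)), nrow = d[3])
  sm <- smooth_columns(flat, window)
  aperm(array(sm, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
}

smooth_vec <- function(x, window) {
  as.numeric(smooth_columns(matrix(x, ncol = 1), window))
}

#' Group active pixels into ROIs
#'
#' Labels 8-connected components of the active mask, then refines each
#' component by trace coherence: the pixel with the largest transient
#' is taken as the component's reference, and pixels whose (lightly
#' smoothed) trace correlates below `corr_min` with the (smoothed)
#' component mean-or-reference trace are removed and regrouped among
#' themselves, so adjacent clusters with unrelated dynamics split into
#' separate ROIs. Components smaller than `min_size_px` are discarded.
#'
#' @param movie numeric array `H x W x T`.
#' @param mask logical matrix from [active_pixel_mask()].
#' @param min_size_px smallest ROI retained, pixels.
#' @param corr_min coherence threshold; `NULL` disables splitting.
#' @param smooth_window moving-average width used for the coherence
#'   correlations.
#' @return An object of class `roi_set`: list with `labels` (integer
#'   `H x W`, 0 = background) and `rois` (tibble `roi`, `n_px`,
#'   `centroid_row`, `centroid_col`, `trace` list-column of mean
#'   traces).
#' @export
group_rois <- function(movie, mask, min_size_px = 4, corr_min = 0.7,
                       smooth_window = 5) {
  stopifnot(all(dim(mask) == dim(movie)[1:2]))
  h <- dim(movie)[1]; w <- dim(movie)[2]; T_ <- dim(movie)[3]
  flat <- matrix(aperm(movie, c(3, 1, 2)), nrow = T_)  # T x (H*W)
  flat_s <- if (smooth_window > 1) smooth_columns(flat, smooth_window)
    else flat

  final <- list()
  refine <- function(pixels) {
    # pixels: linear indices into H*W
    if (length(pixels) == 0) return()
    sub <- matrix(FALSE, h, w)
    sub[pixels] <- TRUE
    comp <- label_components(sub, 8)
    for (id in seq_len(max(comp))) {
      px <- which(comp == id)
      if (length(px) == 0) next
      if (is.null(corr_min) || length(px) < 2) {
        final[[length(final) + 1]] <<- px
        next
      }
      tr <- flat_s[, px, drop = FALSE]
      mean_tr <- rowMeans(tr)
      cc <- if (sd(mean_tr) > 0) {
        suppressWarnings(as.numeric(cor(tr, mean_tr)))
      } else rep(-Inf, length(px))  # e.g. anticorrelated halves cancel
      cc[is.na(cc)] <- 0
      keep <- cc >= corr_min
      if (!any(keep)) {
        # Anticorrelated halves can cancel in the mean; retry against
        # the pixel with the largest transient as reference.
        ref <- which.max(apply(tr, 2, function(v) diff(range(v))))
        cc <- suppressWarnings(as.numeric(cor(tr, tr[, ref])))
        cc[is.na(cc)] <- 0
        keep <- cc >= corr_min
      }
      if (all(keep) || !any(keep)) {
        final[[length(final) + 1]] <<- px
      } else {
        final[[length(final) + 1]] <<- px[keep]
        refine(px[!keep])
      }
    }
  }
  refine(which(mask))

  final <- Filter(function(px) length(px) >= min_size_px, final)
  labels <- matrix(0L, h, w)
  rois <- purrr::imap(final, function(px, i) {
    labels[px] <<- i
    rc <- arrayInd(px, c(h, w))
    tibble::tibble(
      roi = i, n_px = length(px),
      centroid_row = mean(rc[, 1]), centroid_col = mean(rc[, 2]),
      trace = list(rowMeans(flat[, px, drop = FALSE]))
    )
  }) |> purrr::list_rbind()
  if (is.null(rois) || nrow(rois) == 0) {
    rois <- tibble::tibble(roi = integer(), n_px = integer(),
                           centroid_row = numeric(), centroid_col = numeric(),
                           trace = list())
  }
  structure(list(labels = labels, rois = rois), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROI(s), %d active pixel(s) in %dx%d frame\n",
              nrow(x$rois), sum(x$labels > 0), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Active-area fraction
#'
#' Total ROI area relative to the area of labelled inputs: the sum of
#' ROI pixels divided by the pixel count of `total_mask` (for example,
#' the thresholded anatomy of all labelled axons).
#'
#' @param rois a [group_rois()] result.
#' @param total_mask logical matrix of the reference area.
#' @return A single fraction in `[0, 1]` (can exceed 1 if ROIs extend
#'   outside `total_mask`).
#' @export
active_area_fraction <- function(rois, total_mask) {
  if (sum(total_mask) == 0) abort("`total_mask` is empty")
  sum(rois$labels > 0) / sum(total_mask)
}

#' Tally ROIs per anatomical layer
#'
#' Assigns each ROI to the layer containing its (rounded) centroid;
#' if the centroid falls on background the majority layer over the
#' ROI's pixels is used, and ROIs overlapping no layer are counted as
#' `"unassigned"`.
#'
#' @param rois a [group_rois()] result.
#' @param layer_mask integer matrix of layer labels (0 = none), same
#'   shape as the movie frames.
#' @param layer_names optional character vector naming layers `1..K`.
#' @return A tibble `layer`, `n_rois`.
#' @export
layer_tally <- function(rois, layer_mask, layer_names = NULL) {
  stopifnot(all(dim(layer_mask) == dim(rois$labels)))
  assign_one <- function(i) {
    px <- which(rois$labels == i)
    r <- rois$rois[rois$rois$roi == i, ]
    cl <- layer_mask[round(r$centroid_row), round(r$centroid_col)]
    if (cl == 0) {
      vals <- layer_mask[px]
      vals <- vals[vals != 0]
      if (length(vals) == 0) return(0L)
      cl <- as.integer(names(sort(table(vals), decreasing = TRUE))[1])
    }
    as.integer(cl)
  }
  ids <- rois$rois$roi
  layer <- vapply(ids, assign_one, integer(1))
  lab <- function(k) {
    ifelse(k == 0L, "unassigned",
           if (is.null(layer_names)) as.character(k) else layer_names[k])
  }
  tibble::tibble(layer = vapply(layer, lab, character(1))) |>
    dplyr::count(.data$layer, name = "n_rois")
}
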
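# Delimited-text and TIFF interfaces.

#' Read a trace table
#'
#' Reads a delimited table with one row per ROI: metadata columns
#' (anything non-numeric-named, e.g. `roi_id`, `side`, `group`,
#' `animal`, `label`) followed by sample columns whose header is the
#' sample time in seconds. Exported supplementary response tables
#' follow this shape.
#'
#' @param path file path (CSV by default).
#' @param delim field delimiter.
#' @return A long tibble `roi`, `time`, `value` plus any metadata
#'   columns.
#' @export
read_trace_table <- function(path, delim = ",") {
  wide <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  time_cols <- names(wide)[!is.na(suppressWarnings(as.numeric(names(wide))))]
  if (length(time_cols) < 2) abort("no numeric-named sample columns found")
  meta_cols <- setdiff(names(wide), time_cols)
  id <- intersect(c("roi_id", "roi"), meta_cols)
  if (length(id) == 0) {
    wide$roi <- sprintf("roi%03d", seq_len(nrow(wide)))
  } else {
    wide$roi <- as.character(wide[[id[1]]])
    wide[[id[1]]] <- NULL
  }
  wide |>
    tidyr::pivot_longer(dplyr::all_of(time_cols), names_to = "time",
                        values_to = "value") |>
    dplyr::mutate(time = as.numeric(.data$time)) |>
    dplyr::relocate("roi", "time", "value")
}

#' Write a trace table
#'
#' Inverse of [read_trace_table()]: long traces become one row per ROI
#' with sample times as column headers.
#'
#' @param traces long tibble `roi`, `time`, `value`.
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(traces, path, delim = ",") {
  check_trace_table(traces)
  wide <- traces |>
    dplyr::mutate(time = as.character(.data$time)) |>
    tidyr::pivot_wider(names_from = "time", values_from = "value") |>
    dplyr::rename(roi_id = "roi")
  readr::write_delim(wide, path, delim = delim)
  invisible(path)
}

#' Read and write calcium movies as multi-page TIFF
#'
#' Movies are stored as 16-bit multi-page TIFFs scaled to the stack
#' maximum (TIFF floats are restricted to `[0, 1]`); the analysis is
#' invariant to positive gain, so the scaling is immaterial
#' downstream. Masks are single-page TIFFs: logical for
#' [write_mask()], integer labels scaled by `max(mask)` for layer
#' masks.
#'
#' @param path TIFF path.
#' @return `read_movie()`: numeric array `H x W x T` (unit scale).
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
}

#' @rdname read_movie
#' @param movie numeric array `H x W x T` with non-negative values.
#' @export
write_movie <- function(movie, path) {
  mx <- max(movie)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(dim(movie)[3]),
                  function(k) pmax(movie[, , k], 0) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname read_movie
#' @param mask logical or small-integer matrix.
#' @export
write_mask <- function(mask, path) {
  m <- if (is.logical(mask)) mask * 1 else mask / max(max(mask), 1)
  tiff::writeTIFF(m, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname read_movie
#' @param n_levels number of integer levels encoded in the mask file
#'   (1 for a logical mask).
#' @export
read_mask <- function(path, n_levels = 1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  if (n_levels == 1) m >= 0.5 else round(m * n_levels)
}
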
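# Internal numeric helpers shared across modules.

# Linear-interpolation resample of y (sampled at x) onto xout.
resample_linear <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}

# Label 8- (or 4-) connected components of a logical matrix.
# Returns an integer matrix of the same shape; 0 is background.
# Masks here are small (imaging fields of view, 6x4 RF grids), so a
# plain flood fill is adequate.
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  h <- nrow(mask)
  w <- ncol(mask)
  labels <- matrix(0L, h, w)
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  current <- 0L
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (!mask[i, j] || labels[i, j] != 0L) next
      current <- current + 1L
      queue <- matrix(c(i, j), ncol = 2)
      labels[i, j] <- current
      while (nrow(queue) > 0) {
        p <- queue[1, , drop = TRUE]
        queue <- queue[-1, , drop = FALSE]
        for (k in seq_along(dr)) {
          ri <- p[1] + dr[k]
          ci <- p[2] + dc[k]
          if (ri >= 1 && ri <= h && ci >= 1 && ci <= w &&
              mask[ri, ci] && labels[ri, ci] == 0L) {
            labels[ri, ci] <- current
            queue <- rbind(queue, c(ri, ci))
          }
        }
      }
    }
  }
  labels
}

# Stratified fold assignment: within each class, folds are dealt out in
# a seeded random order so every fold sees every class.
stratified_folds <- function(labels, folds, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  assignment <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assignment
}

# Run code under a temporary RNG seed without disturbing the caller's
# random stream (all generators take explicit seeds).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
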
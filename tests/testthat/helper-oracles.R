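# Shared fixtures and independent oracles.

# Wrap a numeric vector as a one-ROI cycle-response tibble.
cycle_tbl <- function(z, dt = 1, roi = "r1") {
  tibble::tibble(roi = roi, t_cycle = (seq_along(z) - 1) * dt, z = z,
                 n_cycles = 1L)
}

# Independent peak/prominence oracle on a cyclic signal.
#
# Local maxima: an index belongs to a peak plateau when scanning
# cyclically left and right past any ties reaches strictly lower
# values on both sides. Prominence: enumerate every strictly higher
# position q and both cyclic arcs to it, take the minimum along each
# arc, and use the best (highest) such minimum as the key col; with no
# higher ground the col is the global minimum. This is a different
# algorithm from the package's descend-both-ways walk.
oracle_peaks <- function(z) {
  n <- length(z)
  if (diff(range(z)) == 0) {
    return(tibble::tibble(idx = integer(), height = numeric(),
                          prominence = numeric()))
  }
  at <- function(i) z[((i - 1) %% n) + 1]
  is_peak_member <- function(i) {
    l <- i - 1
    while (at(l) == z[i] && l > i - n) l <- l - 1
    r <- i + 1
    while (at(r) == z[i] && r < i + n) r <- r + 1
    at(l) < z[i] && at(r) < z[i]
  }
  arc_min <- function(from, to_set) {
    # min over all arcs from `from` to any index in to_set (one
    # direction), returning the best (max) arc minimum
    best <- -Inf
    for (dir in c(1L, -1L)) {
      m <- Inf
      i <- from
      for (s in seq_len(n - 1)) {
        i <- ((i - 1 + dir) %% n) + 1
        if (i %in% to_set) {
          best <- max(best, m)
          break
        }
        m <- min(m, z[i])
      }
    }
    best
  }
  member <- vapply(seq_len(n), is_peak_member, logical(1))
  # one row per plateau: label cyclic runs of adjacent equal members
  grp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!member[i]) next
    if (i > 1 && member[i - 1] && z[i] == z[i - 1]) {
      grp[i] <- grp[i - 1]
    } else {
      cur <- cur + 1L
      grp[i] <- cur
    }
  }
  if (member[n] && member[1] && z[n] == z[1] && !is.na(grp[n]) &&
      grp[n] != grp[1]) {
    grp[grp == grp[n]] <- grp[1]
  }
  out <- list()
  for (g in unique(stats::na.omit(grp))) {
    p <- which(grp == g)[1]
    higher <- which(z > z[p])
    prom <- if (length(higher) == 0) z[p] - min(z)
      else z[p] - arc_min(p, higher)
    out[[length(out) + 1]] <- tibble::tibble(idx = p, height = z[p],
                                             prominence = prom)
  }
  dplyr::bind_rows(out)
}

# Deterministic small labelled dataset reused by classifier tests.
small_dataset <- function(n = 10, noise_sd = 0.2, seed = 42,
                          stim = ramp_stimulus(n_cycles = 5)) {
  simulate_dataset(stim, n_per_class = n,
                   indicator = indicator_spec(noise_sd = noise_sd),
                   seed = seed)
}
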
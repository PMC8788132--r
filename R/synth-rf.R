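# Synthetic convergent receptive-field scenes: retinotopic RGC inputs,
# SMTLs pooling several RGCs (across hemifields), and PyrNs pooling
# several SMTLs plus a direct RGC input, so ground-truth footprints
# grow by union along the circuit.

#' Simulate a convergent receptive-field scene
#'
#' Draws unit footprints on two 6 x 4 hemifield grids: each RGC gets a
#' contiguous patch of `rgc_patch` positions in one hemifield; each
#' SMTL pools `rgc_per_smtl` RGCs (hemifields may mix, giving
#' binocular footprints); each PyrN pools `smtl_per_pyrn` SMTLs plus
#' one direct RGC. Every downstream footprint is the union of its
#' sources' footprints.
#'
#' @param n_rgc,n_smtl,n_pyrn units per tier.
#' @param rgc_per_smtl,smtl_per_pyrn convergence counts.
#' @param rgc_patch positions per RGC footprint (grown by adjacency).
#' @param grid `c(n_rows, n_cols)` per hemifield.
#' @param seed integer seed.
#' @return An object of class `rf_scene`: tibble `units` (`tier`,
#'   `unit`, `sources` list, `footprint` list of two logical matrices
#'   named contra/ipsi) and the grid dimensions.
#' @export
simulate_rf_scene <- function(n_rgc = 12, n_smtl = 6, n_pyrn = 4,
                              rgc_per_smtl = 3, smtl_per_pyrn = 3,
                              rgc_patch = 2, grid = c(4, 6), seed = 1) {
  nr <- grid[1]; nc <- grid[2]
  empty <- function() list(contra = matrix(FALSE, nr, nc),
                           ipsi = matrix(FALSE, nr, nc))
  with_seed(seed, {
    grow_patch <- function(k) {
      cells <- matrix(FALSE, nr, nc)
      r <- sample.int(nr, 1); c <- sample.int(nc, 1)
      cells[r, c] <- TRUE
      while (sum(cells) < k) {
        border <- which(!cells & neighbours8(cells))
        if (length(border) == 0) break
        cells[border[sample.int(length(border), 1)]] <- TRUE
      }
      cells
    }
    rgc <- lapply(seq_len(n_rgc), function(i) {
      fp <- empty()
      side <- sample(c("contra", "ipsi"), 1)
      fp[[side]] <- grow_patch(rgc_patch)
      fp
    })
    union_fp <- function(fps) {
      Reduce(function(a, b) list(contra = a$contra | b$contra,
                                 ipsi = a$ipsi | b$ipsi), fps, empty())
    }
    smtl_src <- lapply(seq_len(n_smtl), function(i)
      sample.int(n_rgc, min(rgc_per_smtl, n_rgc)))
    smtl <- lapply(smtl_src, function(src) union_fp(rgc[src]))
    pyrn_src <- lapply(seq_len(n_pyrn), function(i)
      list(smtl = sample.int(n_smtl, min(smtl_per_pyrn, n_smtl)),
           rgc = sample.int(n_rgc, 1)))
    pyrn <- lapply(pyrn_src, function(src)
      union_fp(c(smtl[src$smtl], rgc[src$rgc])))
    units <- tibble::tibble(
      tier = rep(c("RGC", "SMTL", "PyrN"), c(n_rgc, n_smtl, n_pyrn)),
      unit = c(sprintf("rgc%02d", seq_len(n_rgc)),
               sprintf("smtl%02d", seq_len(n_smtl)),
               sprintf("pyrn%02d", seq_len(n_pyrn))),
      sources = c(rep(list(NULL), n_rgc), smtl_src, pyrn_src),
      footprint = c(rgc, smtl, pyrn)
    )
    structure(list(units = units, grid = grid, seed = seed),
              class = "rf_scene")
  })
}

# 8-neighbourhood dilation helper for patch growth.
neighbours8 <- function(cells) {
  nr <- nrow(cells); nc <- ncol(cells)
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    ro <- rs - dr
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    co <- cs - dc
    out[rs, cs] <- out[rs, cs] | cells[ro, co]
  }
  out
}

#' @export
print.rf_scene <- function(x, ...) {
  cat(sprintf("<rf_scene> %s on a %dx%d grid per hemifield (seed %d)\n",
              paste(sprintf("%d %s", table(x$units$tier)[unique(x$units$tier)],
                            unique(x$units$tier)), collapse = ", "),
              x$grid[1], x$grid[2], x$seed))
  invisible(x)
}

#' Simulate checkerboard trial responses for a scene
#'
#' Plays one seeded checkerboard schedule per hemifield and gives each
#' unit a transient burst (duration `response_s`, convolved with the
#' indicator) whenever the presented square falls inside its
#' footprint, plus Gaussian noise everywhere. Units whose footprint
#' spans both hemifields respond on both displays.
#'
#' @param scene an [simulate_rf_scene()] scene.
#' @param stim_contra,stim_ipsi [checkerboard_stimulus()] objects; the
#'   defaults use the scene grid with distinct presentation orders.
#' @param indicator an [indicator_spec()]; `noise_sd` is in units of
#'   `amplitude`.
#' @param amplitude response amplitude.
#' @param response_s burst duration after square onset, seconds.
#' @param seed integer seed for the noise.
#' @return A list: `responses` (long tibble `tier`, `unit`, `side`,
#'   `time`, `value`) and `schedules` (list contra/ipsi).
#' @export
simulate_rf_responses <- function(scene,
                                  stim_contra = NULL, stim_ipsi = NULL,
                                  indicator = indicator_spec(rate_hz = 1,
                                                             noise_sd = 0.01),
                                  amplitude = 1, response_s = 2, seed = 1) {
  nr <- scene$grid[1]; nc <- scene$grid[2]
  if (is.null(stim_contra)) {
    stim_contra <- checkerboard_stimulus(n_cols = nc, n_rows = nr,
                                         side = "left", seed = scene$seed)
  }
  if (is.null(stim_ipsi)) {
    stim_ipsi <- checkerboard_stimulus(n_cols = nc, n_rows = nr,
                                       side = "right", seed = scene$seed + 1)
  }
  schedules <- list(contra = trial_schedule(stim_contra),
                    ipsi = trial_schedule(stim_ipsi))
  dt <- 1 / indicator$rate_hz
  dur <- max(schedules$contra$t_off, schedules$ipsi$t_off) +
    stim_contra$gap_s
  t <- seq(0, dur - dt / 2, by = dt)
  responses <- with_seed(seed, {
    purrr::pmap(scene$units, function(tier, unit, sources, footprint) {
      purrr::imap(schedules, function(sched, side) {
        fp <- footprint[[side]]
        r <- rep(0, length(t))
        hit <- sched[fp[cbind(sched$row, sched$col)], ]
        for (i in seq_len(nrow(hit))) {
          r[t >= hit$t_on[i] & t < hit$t_on[i] + response_s] <- amplitude
        }
        v <- indicator_convolve(r, indicator) +
          rnorm(length(t), 0, indicator$noise_sd * amplitude)
        tibble::tibble(tier = tier, unit = unit, side = side,
                       time = t, value = v)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
  list(responses = responses, schedules = schedules)
}
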
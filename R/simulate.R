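# Synthetic two-channel movies of a deforming pseudo-animal with full ground
# truth. The generator states the world the rest of the pipeline assumes:
# constant-intensity nuclear spots in the anchor channel, offset cytoplasmic
# cell bodies whose brightness follows an AR(2) calcium kernel in the
# activity channel, smooth non-rigid body deformation with optional fast
# contraction phases, shared-channel multiplicative motion artifacts,
# photobleaching, and plateau-signal nematocyte-like cells.

#' Simulation configuration
#'
#' Defaults describe the reference benchmark: an elongated body of 200
#' neurons (plus 10 nematocyte-like cells) imaged for 1000 frames at 10 Hz.
#' The calcium kernel defaults to a slow-indicator response with ~3-frame
#' rise and ~20-frame decay at 10 Hz, i.e. AR(2) poles
#' `exp(-1/20)` and `exp(-1/3)`.
#'
#' @param n_neurons,n_nematocytes cell counts per class.
#' @param image_shape `(H, W)` in pixels.
#' @param n_frames number of frames `T`.
#' @param frame_rate_hz acquisition rate (10 Hz keeps up with the fastest
#'   contractions).
#' @param deformation_amplitude_px amplitude of the smooth writhing
#'   deformation; also scales the contraction displacement (see
#'   `contraction_factor`).
#' @param contraction_windows list of `c(start, end)` 0-based frame
#'   intervals with fast longitudinal contraction; empty by default (the
#'   non-contracting benchmark).
#' @param contraction_factor positional contraction amplitude at the body
#'   ends, in units of `deformation_amplitude_px`; the default 10 makes
#'   head-region inter-frame displacement exceed typical nearest-neighbour
#'   spacing during short windows, reproducing the hard tracking regime.
#' @param spike_rate_hz per-neuron Poisson spike rate.
#' @param refractory_frames minimal inter-spike interval (default 10
#'   frames = 1 s at 10 Hz): calcium spikes here are discrete events
#'   seconds apart, which is also what the downstream 5-frame merge
#'   window assumes.
#' @param calcium_kernel AR(2) coefficients `c(g1, g2)`; both poles of
#'   `z^2 - g1 z - g2` must lie in (0, 1).
#' @param noise_sigma named per-channel additive Gaussian noise s.d.
#' @param bleach_rate named per-channel exponential photobleaching rate per
#'   frame.
#' @param channel_offset global activity-channel offset `(dy, dx)` in px.
#' @param offset_jitter_sigma s.d. of the fixed per-cell offset jitter
#'   (cytoplasm is not concentric with the nucleus).
#' @param artifact_rate_hz rate of local axial-motion intensity dips.
#' @param artifact_depth dip depth in (0, 1); both channels are multiplied
#'   by the same local factor `1 - depth`.
#' @param min_spacing_px minimal cell spacing enforced at t = 0. Cells
#'   are space-filling: two somata of ~10 px diameter (`cell_sigma_px` 4,
#'   FWHM ~9.4 px) cannot sit closer than about one diameter, so the
#'   default is 9 px (somata touching). Nuclei (sigma 2 px) are then close
#'   but resolvable, as in real images; the foot and head clusters still
#'   pack cells against this hard floor while the body column is sparser.
#' @param nuclear_sigma_px,cell_sigma_px Gaussian spot scales of nuclei
#'   (sigma 2 px, a ~5 px diameter nucleus) and cell bodies (sigma 3 px,
#'   the Gaussian equivalent of the ~10 px diameter soma implied by the
#'   standard 5 px extraction radius).
#' @param anchor_amplitude,activity_baseline,activity_amplitude intensity
#'   scales (camera units).
#' @param background constant background level added to both channels.
#' @param rng_seed integer seed; identical configs give identical output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_neurons = 200, n_nematocytes = 10,
                       image_shape = c(256, 384), n_frames = 1000,
                       frame_rate_hz = 10, deformation_amplitude_px = 6,
                       contraction_windows = list(),
                       contraction_factor = 10,
                       spike_rate_hz = 0.1, refractory_frames = 10,
                       calcium_kernel = c(exp(-1/20) + exp(-1/3),
                                          -exp(-1/20) * exp(-1/3)),
                       noise_sigma = c(anchor = 4, activity = 3),
                       bleach_rate = c(anchor = 2e-4, activity = 1e-4),
                       channel_offset = c(3, 2), offset_jitter_sigma = 1,
                       artifact_rate_hz = 0.02, artifact_depth = 0.5,
                       min_spacing_px = 9,
                       nuclear_sigma_px = 2, cell_sigma_px = 3,
                       anchor_amplitude = 80, activity_baseline = 20,
                       activity_amplitude = 30, background = 2,
                       rng_seed = 1) {
  g1 <- calcium_kernel[1]; g2 <- calcium_kernel[2]
  poles <- ar2_poles(g1, g2)
  if (any(abs(Im(poles)) > 1e-9) || any(Re(poles) <= 0) ||
      any(Re(poles) >= 1))
    stopf("calcium_kernel must have both AR(2) poles in (0, 1)")
  if (artifact_depth < 0 || artifact_depth >= 1)
    stopf("artifact_depth must be in [0, 1)")
  stopifnot(spike_rate_hz >= 0, artifact_rate_hz >= 0,
            all(bleach_rate >= 0), all(noise_sigma >= 0),
            n_frames >= 1, frame_rate_hz > 0)
  structure(as.list(environment()), class = "sim_config")
}

ar2_poles <- function(g1, g2) polyroot(c(-g2, -g1, 1))

# body layout: ellipse of cells with denser foot (left) and head (right)
# clusters; returns n x 2 (row, col) positions, 0-based pixel coordinates
sample_body_layout <- function(n, H, W, min_spacing = 4) {
  a <- 0.42 * W; b <- 0.30 * H   # ellipse semi-axes (long axis horizontal)
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  pos <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n && tries < n * 400L) {
    tries <- tries + 1L
    kind <- runif(1)
    u <- if (kind < 0.25) rnorm(1, -0.85, 0.12)
         else if (kind < 0.5) rnorm(1, 0.85, 0.12)
         else runif(1, -0.95, 0.95)
    u <- max(-0.98, min(0.98, u))
    v <- runif(1, -1, 1) * sqrt(1 - u^2)
    cand <- c(cy + v * b, cx + u * a)
    if (placed > 0L) {
      d2 <- (pos[seq_len(placed), 1] - cand[1])^2 +
            (pos[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < min_spacing^2) next
    }
    placed <- placed + 1L
    pos[placed, ] <- cand
  }
  if (placed < n)
    stopf(paste("could not place %d cells with %g px spacing;",
                "use fewer cells or a larger image"), n, min_spacing)
  pos
}

# region label from the initial position along the long body axis
body_region <- function(pos, W) {
  u <- (pos[, 2] - (W - 1) / 2) / (0.42 * W)
  ifelse(u < -0.6, "foot", ifelse(u > 0.6, "head", "body"))
}

# smooth time-varying displacement field: Gaussian-RBF interpolation of
# random smooth control-point trajectories, plus longitudinal contraction
# pulses toward the body centre inside the contraction windows
make_deformation <- function(cfg, base_pos) {
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]; TT <- cfg$n_frames
  gr <- seq(0, H - 1, length.out = 4)
  gc <- seq(0, W - 1, length.out = 6)
  ctrl <- as.matrix(expand.grid(row = gr, col = gc))
  nc <- nrow(ctrl)
  # smooth random trajectories: moving-average filtered Gaussian steps,
  # rescaled to the requested amplitude
  smooth_walk <- function() {
    if (TT < 5 || cfg$deformation_amplitude_px == 0)
      return(matrix(0, TT, nc))
    steps <- matrix(rnorm(TT * nc), TT, nc)
    k <- rep(1 / 51, 51)
    sm <- apply(steps, 2, function(x) conv1d_reflect(cumsum(x), k))
    sm <- sweep(sm, 2, sm[1, ])  # zero displacement at t = 0
    mx <- max(abs(sm), 1e-9)
    sm / mx * cfg$deformation_amplitude_px
  }
  disp_r <- smooth_walk()
  disp_c <- smooth_walk()
  # RBF weights from base cell positions to control points
  sig <- mean(c(diff(gr)[1], diff(gc)[1]))
  d2 <- cross_dist(base_pos, ctrl)^2
  wgt <- exp(-d2 / (2 * sig^2))
  wgt <- wgt / pmax(rowSums(wgt), 1e-12)
  # contraction pulse weight per frame
  contr <- numeric(TT)
  for (w in cfg$contraction_windows) {
    t0 <- w[1]; t1 <- w[2]
    idx <- (t0:t1) + 1L
    contr[idx] <- pmax(contr[idx], sin(pi * (0:(t1 - t0)) / (t1 - t0))^2)
  }
  cx <- (W - 1) / 2; a <- 0.42 * W
  amp_c <- cfg$contraction_factor * cfg$deformation_amplitude_px
  list(ctrl = ctrl, disp_r = disp_r, disp_c = disp_c, wgt = wgt,
       positions_at = function(t) {  # 0-based frame
         p <- base_pos
         p[, 1] <- p[, 1] + wgt %*% disp_r[t + 1L, ]
         p[, 2] <- p[, 2] + wgt %*% disp_c[t + 1L, ]
         if (contr[t + 1L] > 0)
           p[, 2] <- p[, 2] - amp_c * contr[t + 1L] * (p[, 2] - cx) / a
         p[, 1] <- pmin(pmax(p[, 1], 0), H - 1)
         p[, 2] <- pmin(pmax(p[, 2], 0), W - 1)
         p
       })
}

#' Simulate a two-channel movie with ground truth
#'
#' @param cfg a [sim_config()].
#' @return list with elements `anchor` ([movie()]), `activity` ([movie()])
#'   and `truth` (class `ground_truth`: per-cell per-frame positions in both
#'   channels, spike frames, cell classes, body regions, and the
#'   deformation control-point displacements).
#' @export
simulate_movie <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed)
  H <- cfg$image_shape[1]; W <- cfg$image_shape[2]; TT <- cfg$n_frames
  n_cells <- cfg$n_neurons + cfg$n_nematocytes
  base_pos <- sample_body_layout(n_cells, H, W, cfg$min_spacing_px)
  if (n_cells > 1 && min(cross_dist(base_pos, base_pos) +
                         diag(Inf, n_cells)) < 1)
    stopf("cells closer than 1 px at t = 0; use fewer cells")
  cls <- c(rep("NEURON", cfg$n_neurons),
           rep("NEMATOCYTE", cfg$n_nematocytes))
  region <- body_region(base_pos, W)
  def <- make_deformation(cfg, base_pos)

  # per-cell constant activity-channel offset
  offs <- cbind(cfg$channel_offset[1] + rnorm(n_cells,
                                              sd = cfg$offset_jitter_sigma),
                cfg$channel_offset[2] + rnorm(n_cells,
                                              sd = cfg$offset_jitter_sigma))

  # spikes and calcium traces
  g1 <- cfg$calcium_kernel[1]; g2 <- cfg$calcium_kernel[2]
  p_spike <- min(1, cfg$spike_rate_hz / cfg$frame_rate_hz)
  spike_frames <- vector("list", n_cells)
  calcium <- matrix(0, TT, n_cells)
  for (i in seq_len(n_cells)) {
    if (cls[i] == "NEURON") {
      s <- rbinom(TT, 1L, p_spike)
      sf <- which(s == 1L)
      keep <- rep(TRUE, length(sf))
      last <- -Inf
      for (k in seq_along(sf)) {
        if (sf[k] - last < cfg$refractory_frames) keep[k] <- FALSE
        else last <- sf[k]
      }
      s[sf[!keep]] <- 0L
      spike_frames[[i]] <- which(s == 1L) - 1L
      calcium[, i] <- as.numeric(stats::filter(s, c(g1, g2),
                                               method = "recursive"))
    } else {
      onset <- floor(runif(1, 0.1, 0.6) * TT)
      lvl <- numeric(TT)
      lvl[(onset + 1L):TT] <- 2
      spike_frames[[i]] <- integer(0)
      calcium[, i] <- lvl
      attr(spike_frames, "plateau_onsets") <-
        c(attr(spike_frames, "plateau_onsets"), onset)
    }
  }

  # shared-channel motion artifacts: local multiplicative dips
  n_art <- rpois(1, cfg$artifact_rate_hz * TT / cfg$frame_rate_hz)
  artifacts <- if (n_art > 0)
    data.frame(start = floor(runif(n_art, 0, TT - 1)),
               dur = floor(runif(n_art, 3, 11)),
               row = runif(n_art, 0, H - 1), col = runif(n_art, 0, W - 1),
               radius = runif(n_art, 30, 60))
  else data.frame(start = numeric(0), dur = numeric(0), row = numeric(0),
                  col = numeric(0), radius = numeric(0))

  artifact_factor_at <- function(t, pos) {
    fac <- rep(1, nrow(pos))
    if (nrow(artifacts) == 0) return(fac)
    act <- which(artifacts$start <= t & t < artifacts$start + artifacts$dur)
    for (k in act) {
      d2 <- (pos[, 1] - artifacts$row[k])^2 + (pos[, 2] - artifacts$col[k])^2
      fac <- fac * (1 - cfg$artifact_depth *
                      exp(-d2 / (2 * (artifacts$radius[k] / 2)^2)))
    }
    fac
  }

  pos_anchor <- array(NA_real_, c(n_cells, TT, 2))
  pos_activity <- array(NA_real_, c(n_cells, TT, 2))
  anchor_frames <- array(NA_real_, c(TT, H, W))
  activity_frames <- array(NA_real_, c(TT, H, W))
  bl_a <- cfg$bleach_rate[["anchor"]]; bl_g <- cfg$bleach_rate[["activity"]]
  ns_a <- cfg$noise_sigma[["anchor"]]; ns_g <- cfg$noise_sigma[["activity"]]
  zero <- matrix(0, H, W)

  for (t in seq_len(TT) - 1L) {
    p <- def$positions_at(t)
    pa <- cbind(pmin(pmax(p[, 1] + offs[, 1], 0), H - 1),
                pmin(pmax(p[, 2] + offs[, 2], 0), W - 1))
    pos_anchor[, t + 1L, ] <- p
    pos_activity[, t + 1L, ] <- pa
    fac_n <- artifact_factor_at(t, p)
    fac_c <- artifact_factor_at(t, pa)
    # bleach multiplies the whole frame (spots and background alike), so a
    # motion- and noise-free frame t equals frame 0 times the bleach factor
    amp_n <- cfg$anchor_amplitude * fac_n
    fr_a <- add_gaussian_spots_cpp(zero, p, amp_n, cfg$nuclear_sigma_px)
    fr_a <- (fr_a + cfg$background) * exp(-bl_a * t)
    amp_c <- (cfg$activity_baseline +
                cfg$activity_amplitude * calcium[t + 1L, ]) * fac_c
    fr_g <- add_gaussian_spots_cpp(zero, pa, amp_c, cfg$cell_sigma_px)
    fr_g <- (fr_g + cfg$background) * exp(-bl_g * t)
    if (ns_a > 0) fr_a <- fr_a + matrix(rnorm(H * W, sd = ns_a), H, W)
    if (ns_g > 0) fr_g <- fr_g + matrix(rnorm(H * W, sd = ns_g), H, W)
    anchor_frames[t + 1L, , ] <- pmax(fr_a, 0)
    activity_frames[t + 1L, , ] <- pmax(fr_g, 0)
  }

  truth <- structure(list(positions_anchor = pos_anchor,
                          positions_activity = pos_activity,
                          spike_frames = spike_frames,
                          calcium = calcium,
                          cell_class = cls, region = region,
                          artifacts = artifacts,
                          offsets = offs,
                          n_frames = TT, image_shape = c(H, W),
                          config = cfg),
                     class = "ground_truth")
  list(anchor = movie(anchor_frames, cfg$frame_rate_hz, "anchor"),
       activity = movie(activity_frames, cfg$frame_rate_hz, "activity"),
       truth = truth)
}

#' Fragment ground-truth trajectories into tracklets
#'
#' Emulates the premature track terminations of frame-to-frame trackers:
#' each cell's trajectory is split, with probability `gap_rate`, at one
#' uniformly chosen interior frame, removing `gap_length` frames
#' (`gap_rate = 1` forces exactly one split per cell; apply repeatedly for
#' multiple gaps). Cells whose trajectory is not longer than the gap yield a
#' single unsplit tracklet.
#'
#' @param truth a `ground_truth` object.
#' @param gap_rate per-cell split probability in `[0, 1]`.
#' @param gap_length gap length in frames.
#' @param rng_seed integer seed.
#' @return list of [track()] tracklets; attribute `true_cell` maps each
#'   tracklet to its ground-truth cell index (1-based).
#' @export
fragment_tracks <- function(truth, gap_rate, gap_length, rng_seed = 1) {
  stopifnot(gap_rate >= 0, gap_rate <= 1, gap_length >= 1)
  set.seed(rng_seed)
  TT <- truth$n_frames
  n_cells <- dim(truth$positions_anchor)[1]
  out <- list()
  true_cell <- integer(0)
  tid <- 0L
  for (i in seq_len(n_cells)) {
    pos <- truth$positions_anchor[i, , , drop = FALSE]
    dim(pos) <- c(TT, 2)
    split <- runif(1) < gap_rate && TT > gap_length + 2
    if (!split) {
      tid <- tid + 1L
      out[[length(out) + 1L]] <- track(tid, 0L, pos)
      true_cell <- c(true_cell, i)
      next
    }
    s <- sample(seq_len(TT - gap_length - 2L), 1L)  # last frame of part 1
    tid <- tid + 1L
    out[[length(out) + 1L]] <- track(tid, 0L, pos[1:s, , drop = FALSE])
    true_cell <- c(true_cell, i)
    tid <- tid + 1L
    out[[length(out) + 1L]] <-
      track(tid, s + gap_length,
            pos[(s + gap_length + 1L):TT, , drop = FALSE])
    true_cell <- c(true_cell, i)
  }
  attr(out, "true_cell") <- true_cell
  out
}

#' Write ground truth to plain-text CSVs
#'
#' Writes `positions.csv`, `spikes.csv` and `cells.csv` under `dir`.
#'
#' @param truth a `ground_truth`.
#' @param dir output directory (created if needed).
#' @export
write_truth_csv <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  TT <- truth$n_frames
  n_cells <- dim(truth$positions_anchor)[1]
  pos <- do.call(rbind, lapply(seq_len(n_cells), function(i)
    data.frame(cell = i, frame = seq_len(TT) - 1L,
               row_anchor = truth$positions_anchor[i, , 1],
               col_anchor = truth$positions_anchor[i, , 2],
               row_activity = truth$positions_activity[i, , 1],
               col_activity = truth$positions_activity[i, , 2])))
  write.csv(format_num_df(pos), file.path(dir, "positions.csv"),
            row.names = FALSE, quote = FALSE)
  sp <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    f <- truth$spike_frames[[i]]
    if (length(f)) data.frame(cell = i, frame = f) else NULL
  }))
  if (is.null(sp)) sp <- data.frame(cell = integer(0), frame = integer(0))
  write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(cell = seq_len(n_cells), class = truth$cell_class,
                       region = truth$region),
            file.path(dir, "cells.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
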
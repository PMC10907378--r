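# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small deforming two-channel movie with spikes (dense-ish, noisy)
fix_sim_small <- function() memo("sim_small", {
  simulate_movie(sim_config(
    n_neurons = 15, n_nematocytes = 2, image_shape = c(140, 220),
    n_frames = 250, min_spacing_px = 12, deformation_amplitude_px = 3,
    spike_rate_hz = 0.12, rng_seed = 42))
})

# sparse, well-separated spots for detection tests
fix_sim_sparse <- function() memo("sim_sparse", {
  simulate_movie(sim_config(
    n_neurons = 40, n_nematocytes = 0, image_shape = c(200, 300),
    n_frames = 3, min_spacing_px = 12, rng_seed = 11))
})

truth_detections <- function(truth, t) {
  pos <- matrix(truth$positions_anchor[, t + 1L, ], ncol = 2)
  frame_detections(t, pos, rep(5, nrow(pos)))
}

# noiseless rigidly-translating movie rendered directly (no generator noise)
render_movie <- function(positions_list, H, W, amp = 50, sigma = 2,
                         channel = "anchor") {
  frames <- lapply(positions_list, function(p)
    spiketrack:::add_gaussian_spots_cpp(matrix(0, H, W),
                                        matrix(p, ncol = 2),
                                        rep(amp, nrow(matrix(p, ncol = 2))),
                                        sigma))
  movie(frames, channel_name = channel)
}

# brute-force minimal assignment cost by enumerating all permutations
brute_lap <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(n)))
    best <- min(best, sum(cost[cbind(seq_len(n), p)]))
  best
}

# brute-force optimum of the stitching objective: enumerate all feasible
# link subsets; objective = sum of link costs + eta/2 per unlinked endpoint
brute_stitch_objective <- function(costs, eta) {
  N <- nrow(costs)
  pairs <- which(is.finite(costs), arr.ind = TRUE)
  best <- N * eta  # no links at all
  np <- nrow(pairs)
  if (np == 0) return(best)
  for (mask in 0:(2^np - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(np) - 1)) > 0)
    if (length(sel) > 1) {
      if (anyDuplicated(pairs[sel, 1]) || anyDuplicated(pairs[sel, 2]))
        next
    }
    lc <- sum(costs[pairs[sel, , drop = FALSE]])
    n_unlinked_ends <- N - length(sel)
    n_unlinked_starts <- N - length(sel)
    best <- min(best, lc + eta / 2 * (n_unlinked_ends + n_unlinked_starts))
  }
  best
}

# objective value of a stitch() result under the same convention
stitch_objective <- function(costs, links, eta) {
  N <- nrow(costs)
  lc <- if (nrow(links)) sum(costs[links]) else 0
  lc + eta / 2 * (2 * N - 2 * nrow(links))
}

# generic convex-programming oracle for the penalized problem:
# box-constrained L-BFGS-B on s >= 0 with analytic gradient
oracle_deconv <- function(y, g1, g2, lambda) {
  TT <- length(y)
  K <- function(s) as.numeric(stats::filter(s, c(g1, g2),
                                            method = "recursive"))
  Kt <- function(r) rev(as.numeric(stats::filter(rev(r), c(g1, g2),
                                                 method = "recursive")))
  fn <- function(s) { r <- K(s) - y; 0.5 * sum(r^2) + lambda * sum(s) }
  gr <- function(s) Kt(K(s) - y) + lambda
  fit <- optim(rep(0, TT), fn, gr, method = "L-BFGS-B", lower = 0,
               control = list(maxit = 2000, factr = 10))
  list(s = fit$par, objective = fit$value)
}

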
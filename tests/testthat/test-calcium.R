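# Sub-ROI calcium linking and signal extraction.

euclid_px <- function(a, b) sqrt(sum((a - b)^2))

spots_frame <- function(H, W, pos, amps, sigma = 3) {
  spiketrack:::add_gaussian_spots_cpp(matrix(0, H, W),
                                      matrix(pos, ncol = 2), amps, sigma)
}

test_that("a single centred blob is the first ROI maximum", {
  roi <- spots_frame(25, 25, c(12, 12), 40)
  mx <- find_roi_maxima(roi, subroi_params())
  expect_equal(unname(mx[1, ]), c(12, 12))
})

test_that("the prior ranks a centred blob above a brighter offset one", {
  p <- subroi_params()
  roi <- spots_frame(25, 25, rbind(c(12, 12), c(12, 20)), c(30, 45))
  mx <- find_roi_maxima(roi, p)
  # arithmetic oracle on the two prior-weighted peak values
  sm <- spiketrack:::gaussian_blur2d(roi, p$smooth_sigma_px)
  pri <- exp(-outer((0:24 - 12)^2, (0:24 - 12)^2, "+") /
               (2 * p$prior_sigma_px^2))
  w <- sm * pri
  expect_gt(w[13, 13], w[13, 21])
  # first candidate is the centre blob's peak (the neighbour's tail can
  # shift the smoothed peak by a pixel)
  expect_lt(sqrt(sum((mx[1, ] - c(12, 12))^2)), 1.5)
  # the offset blob is still reported as a later candidate near (12, 20)
  d2 <- (mx[-1, 1] - 12)^2 + (mx[-1, 2] - 20)^2
  expect_lt(min(d2), 4)
})

test_that("a constant patch yields the prior's peak (patch centre) first", {
  mx <- find_roi_maxima(matrix(5, 25, 25), subroi_params())
  expect_equal(unname(mx[1, ]), c(12, 12))
})

test_that("aligned channels track the nucleus to sub-pixel accuracy", {
  pos <- c(30.3, 40.7)
  frames <- replicate(10, spots_frame(60, 80, pos, 35, 3),
                      simplify = FALSE)
  act <- movie(frames, channel_name = "activity")
  tr <- track(1, 0, matrix(rep(pos, 10), 10, 2, byrow = TRUE))
  cp <- track_calcium_positions(tr, act, subroi_params())
  err <- sqrt(rowSums(sweep(cp, 2, pos)^2))
  expect_true(all(err <= 0.5))
})

test_that("a constant channel offset is recovered within 1 px", {
  cfg <- sim_config(n_neurons = 10, n_nematocytes = 0,
                    image_shape = c(120, 200), n_frames = 60,
                    min_spacing_px = 14, deformation_amplitude_px = 2,
                    offset_jitter_sigma = 0, channel_offset = c(3, 2),
                    rng_seed = 31)
  sim <- simulate_movie(cfg)
  errs <- vapply(1:5, function(i) {
    tr <- track(i, 0, matrix(sim$truth$positions_anchor[i, , ], ncol = 2))
    cp <- track_calcium_positions(tr, sim$activity, subroi_params())
    est <- colMeans(cp - matrix(sim$truth$positions_anchor[i, , ],
                                ncol = 2))
    sqrt(sum((est - c(3, 2))^2))
  }, 0.0)
  expect_true(all(errs < 1))
})

test_that("the EMA limits the jump toward a transient outlier", {
  # wide suppression so the outlier is unambiguously the nearest candidate
  p <- subroi_params(ema_rate = 0.5, suppression_radius_px = 12)
  pos <- c(30, 30)
  quiet <- spots_frame(60, 80, pos, 35, 3)
  outlier <- spots_frame(60, 80, rbind(c(30, 40)), 200, 3)  # 10 px away
  act <- movie(list(quiet, quiet, outlier, quiet),
               channel_name = "activity")
  tr <- track(1, 0, matrix(rep(pos, 4), 4, 2, byrow = TRUE))
  cp <- track_calcium_positions(tr, act, p)
  jump <- euclid_px(cp[3, ], cp[2, ])
  cand_dist <- euclid_px(c(30, 40), cp[2, ])
  # the EMA caps the per-frame displacement at ema_rate times the
  # candidate distance (the candidate itself sits at or just inside the
  # outlier, so the bound is nearly attained)
  expect_lte(jump, p$ema_rate * cand_dist + 1e-6)
  expect_gt(jump, 0.3 * p$ema_rate * cand_dist)
  expect_gt(cp[3, 2], cp[2, 2])  # moved toward the outlier, not onto it
  expect_lt(jump, cand_dist)
})

test_that("uniform images give constant traces equal to the value", {
  act <- movie(replicate(5, matrix(7.5, 40, 40), simplify = FALSE),
               channel_name = "activity")
  anc <- movie(replicate(5, matrix(7.5, 40, 40), simplify = FALSE))
  tr <- track(1, 0, matrix(rep(c(20, 20), 5), 5, 2, byrow = TRUE))
  s <- extract_signals(tr, anc, act, subroi_params())
  expect_equal(s$control, rep(7.5, 5))
  expect_equal(s$calcium_raw, rep(7.5, 5))
})

test_that("sub-ROI extraction isolates one cell where a full ROI mixes two", {
  # two adjacent cells 10 px apart; only the tracked one fires (frames
  # 10-19), the neighbour fires later (frames 30-39)
  TT <- 50
  own <- c(40, 40); other <- c(40, 50)
  own_amp <- rep(20, TT); own_amp[11:20] <- 60
  oth_amp <- rep(20, TT); oth_amp[31:40] <- 80
  frames <- lapply(1:TT, function(t)
    spots_frame(80, 100, rbind(own, other), c(own_amp[t], oth_amp[t]), 3))
  act <- movie(frames, channel_name = "activity")
  anc <- movie(lapply(1:TT, function(t)
    spots_frame(80, 100, rbind(own), 40, 2)))
  tr <- track(1, 0, matrix(rep(own, TT), TT, 2, byrow = TRUE))
  s <- extract_signals(tr, anc, act, subroi_params())
  own_win <- 11:20; oth_win <- 31:40; base_win <- 1:10
  base <- mean(s$calcium_raw[base_win])
  own_rise <- mean(s$calcium_raw[own_win]) - base
  oth_rise <- mean(s$calcium_raw[oth_win]) - base
  expect_gt(own_rise, 10)
  # the neighbour's transient must not leak into the sub-ROI trace
  # (only its faint disc-edge tail remains, < 10% of the own transient)
  expect_lt(abs(oth_rise), 0.1 * own_rise)
  # whereas the naive full-ROI mean reports both transients
  naive <- vapply(1:TT, function(t) {
    f <- frames[[t]]
    mean(f[(own[1] - 12):(own[1] + 12) + 1, (own[2] - 12):(own[2] + 12) + 1])
  }, 0.0)
  nb <- mean(naive[base_win])
  expect_gt(mean(naive[own_win]) - nb, 1)
  expect_gt(mean(naive[oth_win]) - nb, 1)
})

test_that("calcium positions always stay inside the image", {
  sim <- fix_sim_small()
  tr <- track(1, 0, matrix(sim$truth$positions_anchor[3, 1:50, ],
                           ncol = 2))
  cp <- track_calcium_positions(tr, sim$activity, subroi_params())
  expect_true(all(cp[, 1] >= 0 & cp[, 1] <= 139))
  expect_true(all(cp[, 2] >= 0 & cp[, 2] <= 219))
})

test_that("tracks outside the movie are a contract violation", {
  act <- movie(array(1, c(5, 20, 20)), channel_name = "activity")
  tr <- track(1, 3, matrix(rep(c(5, 5), 4), 4, 2, byrow = TRUE))
  expect_error(extract_signals(tr, act, act, subroi_params()),
               "outside the movie")
})
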
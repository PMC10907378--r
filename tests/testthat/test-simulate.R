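# Synthetic movie generator: determinism, stated identities, spike
# statistics, and track fragmentation.

test_that("identical configs give bit-identical movies", {
  cfg <- sim_config(n_neurons = 8, n_nematocytes = 1,
                    image_shape = c(60, 90), n_frames = 12, rng_seed = 5)
  a <- simulate_movie(cfg)
  b <- simulate_movie(cfg)
  expect_identical(a$anchor$frames, b$anchor$frames)
  expect_identical(a$activity$frames, b$activity$frames)
  expect_identical(a$truth$positions_anchor, b$truth$positions_anchor)
  expect_identical(a$truth$spike_frames, b$truth$spike_frames)
})

test_that("zero deformation/noise/artifacts freeze positions and frames", {
  cfg <- sim_config(n_neurons = 6, n_nematocytes = 0,
                    image_shape = c(60, 90), n_frames = 10,
                    deformation_amplitude_px = 0, artifact_rate_hz = 0,
                    noise_sigma = c(anchor = 0, activity = 0),
                    rng_seed = 2)
  sim <- simulate_movie(cfg)
  for (t in 1:9)
    expect_equal(sim$truth$positions_anchor[, t + 1, ],
                 sim$truth$positions_anchor[, 1, ])
  bl <- cfg$bleach_rate[["anchor"]]
  for (t in c(3, 9))
    expect_equal(sim$anchor$frames[t + 1, , ],
                 sim$anchor$frames[1, , ] * exp(-bl * t), tolerance = 1e-12)
})

test_that("without spikes the activity trace is baseline x bleach only", {
  cfg <- sim_config(n_neurons = 4, n_nematocytes = 0,
                    image_shape = c(60, 90), n_frames = 20,
                    deformation_amplitude_px = 0, artifact_rate_hz = 0,
                    noise_sigma = c(anchor = 0, activity = 0),
                    spike_rate_hz = 0, rng_seed = 3)
  sim <- simulate_movie(cfg)
  expect_true(all(sim$truth$calcium == 0))
  i <- 1
  p <- sim$truth$positions_activity[i, 1, ]
  v0 <- sim$activity$frames[1, round(p[1]) + 1, round(p[2]) + 1]
  bl <- cfg$bleach_rate[["activity"]]
  for (t in c(5, 19)) {
    vt <- sim$activity$frames[t + 1, round(p[1]) + 1, round(p[2]) + 1]
    expect_equal(vt, v0 * exp(-bl * t), tolerance = 1e-10)
  }
})

test_that("total spike count falls in the 3-sigma Poisson interval", {
  cfg <- sim_config(n_neurons = 50, n_nematocytes = 0,
                    image_shape = c(120, 260), n_frames = 1000,
                    min_spacing_px = 6, spike_rate_hz = 0.1,
                    noise_sigma = c(anchor = 0, activity = 0),
                    artifact_rate_hz = 0, deformation_amplitude_px = 0,
                    rng_seed = 9)
  sim <- simulate_movie(cfg)
  total <- sum(lengths(sim$truth$spike_frames))
  lambda <- 50 * 0.1 * 100  # n * rate * duration_s = 500
  expect_gt(total, lambda - 3 * sqrt(lambda))
  expect_lt(total, lambda + 3 * sqrt(lambda))
  # calcium obeys the AR(2) recursion exactly (residual = spike indicator)
  g <- cfg$calcium_kernel
  for (i in c(1, 25)) {
    c_ <- sim$truth$calcium[, i]
    s <- numeric(1000)
    s[sim$truth$spike_frames[[i]] + 1] <- 1
    resid <- c_ - g[1] * c(0, head(c_, -1)) - g[2] * c(0, 0, head(c_, -2))
    expect_equal(resid, s, tolerance = 1e-10)
  }
})

test_that("ground truth conserves trajectories and labels nematocytes", {
  sim <- fix_sim_small()
  expect_false(anyNA(sim$truth$positions_anchor))
  expect_equal(dim(sim$truth$positions_anchor)[1], 17)
  expect_equal(sum(sim$truth$cell_class == "NEMATOCYTE"), 2)
  nem <- which(sim$truth$cell_class == "NEMATOCYTE")
  for (i in nem) {
    expect_length(sim$truth$spike_frames[[i]], 0)
    tr <- sim$truth$calcium[, i]
    expect_true(all(diff(tr) >= 0))          # single plateau onset
    expect_equal(length(unique(tr)), 2)      # off then plateau
  }
})

test_that("overcrowded layouts raise a generation error", {
  cfg <- sim_config(n_neurons = 80, n_nematocytes = 0,
                    image_shape = c(40, 60), n_frames = 2,
                    min_spacing_px = 0.2, rng_seed = 1)
  expect_error(simulate_movie(cfg), "closer than 1 px|fewer cells")
})

test_that("fragment_tracks covers gap_rate 0, 1, and determinism", {
  sim <- fix_sim_small()
  whole <- fragment_tracks(sim$truth, gap_rate = 0, gap_length = 10)
  expect_length(whole, 17)
  expect_true(all(vapply(whole, function(x)
    x$start_frame == 0 && x$end_frame == 249, TRUE)))

  split <- fragment_tracks(sim$truth, gap_rate = 1, gap_length = 10,
                           rng_seed = 6)
  expect_length(split, 34)
  tc <- attr(split, "true_cell")
  for (i in 1:17) {
    parts <- split[tc == i]
    expect_length(parts, 2)
    covered <- sum(vapply(parts, function(p)
      p$end_frame - p$start_frame + 1L, 0L))
    expect_equal(covered, 250L - 10L)
    expect_lt(parts[[1]]$end_frame, parts[[2]]$start_frame)
  }
  split2 <- fragment_tracks(sim$truth, gap_rate = 1, gap_length = 10,
                            rng_seed = 6)
  expect_identical(lapply(split, `[[`, "positions"),
                   lapply(split2, `[[`, "positions"))
})

test_that("gaps longer than the trajectory leave it unsplit", {
  cfg <- sim_config(n_neurons = 3, n_nematocytes = 0,
                    image_shape = c(60, 90), n_frames = 8, rng_seed = 4)
  sim <- simulate_movie(cfg)
  out <- fragment_tracks(sim$truth, gap_rate = 1, gap_length = 10)
  expect_length(out, 3)
})

test_that("ground truth CSVs round-trip through the reader", {
  sim <- fix_sim_small()
  dir <- withr::local_tempdir()
  write_truth_csv(sim$truth, dir)
  back <- read_truth_dir(dir)
  expect_equal(back$positions_anchor, sim$truth$positions_anchor,
               tolerance = 1e-6)
  expect_equal(back$cell_class, sim$truth$cell_class)
  expect_equal(back$spike_frames, sim$truth$spike_frames,
               ignore_attr = TRUE)
})
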
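# Thin-plate-spline fitting, propagation, stitch costs, and the global
# linking assignment.

test_that("TPS reproduces identity and translations exactly at any alpha", {
  set.seed(12)
  src <- matrix(runif(24, 0, 100), 12, 2)
  for (alpha in c(0, 10, 1000)) {
    id <- tps_fit(src, src, alpha)
    q <- matrix(runif(10, 0, 100), 5, 2)
    expect_equal(tps_apply(id, q), q, tolerance = 1e-8)
    tr <- tps_fit(src, src + matrix(c(3, -7), 12, 2, byrow = TRUE), alpha)
    expect_equal(tps_apply(tr, q),
                 q + matrix(c(3, -7), 5, 2, byrow = TRUE),
                 tolerance = 1e-8)
  }
})

test_that("a known quadratic warp is learned to < 0.1 px held out", {
  set.seed(13)
  warp <- function(p) cbind(p[, 1] + 1e-3 * p[, 2]^2,
                            p[, 2] + 2e-3 * p[, 1] * p[, 2] / 10)
  src <- matrix(runif(60, 10, 90), 30, 2)
  fit <- tps_fit(src, warp(src), alpha = 0)
  held <- matrix(runif(20, 20, 80), 10, 2)
  err <- sqrt(rowSums((tps_apply(fit, held) - warp(held))^2))
  expect_lt(max(err), 0.1)
})

test_that("degenerate control points raise an informative error", {
  src <- cbind(1:10, 2 * (1:10) + 3)  # collinear
  expect_error(tps_fit(src, src, 0), "degenerate|affine")
  expect_error(tps_fit(matrix(1, 5, 2), matrix(1, 5, 2), 0), "degenerate")
})

make_translating_tracklets <- function(v = c(1, 0), TT = 20,
                                       gap = list(a = c(0, 9), b = c(14, 19))) {
  # 8 background tracklets alive the whole time, translating at v px/frame
  set.seed(14)
  base <- matrix(runif(16, 0, 60), 8, 2)
  out <- list()
  for (i in 1:8) {
    pos <- cbind(base[i, 1] + v[1] * (0:(TT - 1)),
                 base[i, 2] + v[2] * (0:(TT - 1)))
    out[[i]] <- track(i, 0, pos)
  }
  # one split trajectory: part a then part b after a gap
  start <- c(30, 30)
  pos_a <- cbind(start[1] + v[1] * (gap$a[1]:gap$a[2]),
                 start[2] + v[2] * (gap$a[1]:gap$a[2]))
  pos_b <- cbind(start[1] + v[1] * (gap$b[1]:gap$b[2]),
                 start[2] + v[2] * (gap$b[1]:gap$b[2]))
  out[[9]] <- track(9, gap$a[1], pos_a)
  out[[10]] <- track(10, gap$b[1], pos_b)
  out
}

test_that("propagation is exact under stationary and translating fields", {
  still <- make_translating_tracklets(v = c(0, 0))
  fwd <- propagate_forward(still[[9]], still, stitch_params(), 5,
                           n_total = 20)
  expect_equal(fwd[, "row"], rep(30, 6), ignore_attr = TRUE)
  expect_equal(fwd[, "col"], rep(30, 6), ignore_attr = TRUE)

  mov <- make_translating_tracklets(v = c(1, 0))
  fwd <- propagate_forward(mov[[9]], mov, stitch_params(), 5, n_total = 20)
  expect_equal(fwd[, "row"], 39 + 0:5, ignore_attr = TRUE)
  expect_equal(fwd[, "col"], rep(30, 6), ignore_attr = TRUE)
  bwd <- propagate_backward(mov[[10]], mov, stitch_params(), 5,
                            n_total = 20)
  expect_equal(bwd[, "row"], 44 - 0:5, ignore_attr = TRUE)
})

test_that("propagation crosses a 10-frame gap within 1 px on a deforming movie", {
  sim <- fix_sim_small()
  frag <- fragment_tracks(sim$truth, gap_rate = 1, gap_length = 10,
                          rng_seed = 5)
  tc <- attr(frag, "true_cell")
  sp <- stitch_params()
  # pick the first three cells' leading fragments and propagate over the gap
  checked <- 0
  for (cell in 1:3) {
    parts <- which(tc == cell)
    a <- frag[[parts[1]]]; b <- frag[[parts[2]]]
    fwd <- propagate_forward(a, frag, sp, b$start_frame - a$end_frame,
                             n_total = 250)
    f <- b$start_frame
    est <- fwd[fwd[, "frame"] == f, c("row", "col")]
    if (length(est) == 0) next
    true_pos <- sim$truth$positions_anchor[cell, f + 1, ]
    expect_lt(sqrt(sum((est - true_pos)^2)), 1)
    checked <- checked + 1
  }
  expect_gte(checked, 2)
})

test_that("stitch costs: split trajectory ~0, overlap forbidden, hand value", {
  mov <- make_translating_tracklets(v = c(1, 0))
  cm <- build_stitch_costs(mov, stitch_params(max_gap_frames = 10))
  expect_lt(cm$costs[9, 10], 1e-6)       # true continuation
  expect_true(is.infinite(cm$costs[1, 2]))  # temporally overlapping
  expect_true(all(is.infinite(diag(cm$costs))))
  # hand-computable value: tracklet 10 backward-propagated to frame 9 sits
  # at row 39, col 30; a fictitious tracklet at constant offset would see
  # the distance between the propagated rows; here the true pair's
  # forward and backward estimates coincide frame by frame, so the minimal
  # distance is 0; shifting part b by (0, 5) must give exactly 5
  shifted <- mov
  shifted[[10]] <- track(10, 14, mov[[10]]$positions +
                           matrix(c(0, 5), 6, 2, byrow = TRUE))
  cm2 <- build_stitch_costs(shifted, stitch_params(max_gap_frames = 10))
  expect_equal(cm2$costs[9, 10], 5, tolerance = 1e-6)
})

test_that("far-apart tracklets (costs above eta) stay unmerged", {
  mov <- make_translating_tracklets(v = c(0, 0))
  shifted <- mov
  shifted[[10]] <- track(10, 14, mov[[10]]$positions +
                           matrix(c(0, 8), 6, 2, byrow = TRUE))
  res <- stitch(shifted, stitch_params(eta_px = 5, max_gap_frames = 10))
  links <- attr(res, "links")
  expect_equal(nrow(links), 0)
  expect_length(res, 10)
})

test_that("assignment cost equals the exhaustive optimum (<= 6 tracklets)", {
  set.seed(15)
  for (rep in 1:5) {
    N <- 4
    spans <- list(c(0, 4), c(6, 10), c(12, 16), c(18, 22))
    costs <- matrix(Inf, N, N)
    for (i in 1:N) for (j in 1:N)
      if (spans[[j]][1] > spans[[i]][2]) costs[i, j] <- runif(1, 0, 8)
    links <- spiketrack:::solve_link_assignment(costs, eta_px = 5)
    expect_equal(stitch_objective(costs, links, 5),
                 brute_stitch_objective(costs, 5), tolerance = 1e-9)
  }
})

test_that("stitching restores fragmented synthetic identities", {
  sim <- fix_sim_small()
  frag <- fragment_tracks(sim$truth, gap_rate = 1, gap_length = 10,
                          rng_seed = 5)
  tc <- attr(frag, "true_cell")
  res <- stitch(frag, stitch_params())  # alpha = 10, eta = 5
  expect_lte(length(res), length(frag))
  n_cells <- max(tc)
  good <- 0
  for (tr in res) {
    cells <- unique(tc[tr$parent_tracklets])
    if (length(cells) == 1 && length(tr$parent_tracklets) == 2 &&
        tr$start_frame == 0 && tr$end_frame == 249)
      good <- good + 1
  }
  expect_gte(good / n_cells, 0.95)
  # conservation: stitching adds only INTERPOLATED frames
  det_in <- sum(vapply(frag, function(x) sum(x$status == "DETECTED"), 0L))
  det_out <- sum(vapply(res, function(x) sum(x$status == "DETECTED"), 0L))
  expect_equal(det_in, det_out)
  # no temporally overlapping links
  links <- attr(res, "links")
  for (k in seq_len(nrow(links)))
    expect_gt(frag[[links[k, 2]]]$start_frame,
              frag[[links[k, 1]]]$end_frame)
})

test_that("the link count grows monotonically with eta", {
  mov <- make_translating_tracklets(v = c(0, 0))
  # shift part b so the only admissible link has cost exactly 5 px
  mov[[10]] <- track(10, 14, mov[[10]]$positions +
                       matrix(c(0, 5), 6, 2, byrow = TRUE))
  counts <- vapply(c(1e-9, 1, 4, 20), function(eta) {
    res <- stitch(mov, stitch_params(eta_px = eta, max_gap_frames = 10))
    nrow(attr(res, "links"))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0L)  # eta -> 0+: no links
  expect_equal(counts[4], 1L)  # eta above the cost: link formed
})
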
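# A-trous wavelet decomposition, thresholded detection, distance-matched
# metrics, and grid-search calibration.

# brute-force separable B3 convolution oracle (direct O(n k) sums with
# reflect padding), independent of the shift-and-add implementation
brute_b3_smooth <- function(img, scale) {
  d <- 2^(scale - 1)
  taps <- c(1, 4, 6, 4, 1) / 16
  offs <- c(-2, -1, 0, 1, 2) * d
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  H <- nrow(img); W <- ncol(img)
  tmp <- matrix(0, H, W)
  for (r in 1:H) for (k in 1:5)
    tmp[r, ] <- tmp[r, ] + taps[k] * img[refl(r + offs[k], H), ]
  out <- matrix(0, H, W)
  for (c in 1:W) for (k in 1:5)
    out[, c] <- out[, c] + taps[k] * tmp[, refl(c + offs[k], W)]
  out
}

test_that("constant images give zero planes and the input as residual", {
  img <- matrix(3.7, 20, 24)
  dec <- iuwt_decompose(img, 3)
  for (p in dec$planes) expect_equal(max(abs(p)), 0)
  expect_equal(dec$residual, img)
})

test_that("planes plus residual reconstruct the input to 1e-9 (property)", {
  set.seed(10)
  for (rep in 1:5) {
    img <- matrix(runif(40 * 50, 0, 100), 40, 50)
    dec <- iuwt_decompose(img, 4)
    rec <- Reduce(`+`, dec$planes) + dec$residual
    expect_lt(max(abs(rec - img)) / max(abs(img)), 1e-9)
  }
})

test_that("impulse planes match the brute-force convolution oracle", {
  img <- matrix(0, 33, 33); img[17, 17] <- 1
  dec <- iuwt_decompose(img, 3)
  c_prev <- img
  for (j in 1:3) {
    c_j <- brute_b3_smooth(c_prev, j)
    expect_equal(dec$planes[[j]], c_prev - c_j, tolerance = 1e-12)
    c_prev <- c_j
  }
  expect_equal(dec$residual, c_prev, tolerance = 1e-12)
})

test_that("decomposition refuses scales beyond the image support", {
  expect_error(iuwt_decompose(matrix(0, 8, 8), 4), "maximum feasible")
})

test_that("an all-zero frame yields no detections", {
  det <- detect_wavelet(matrix(0, 30, 30), wavelet_params(2, 3))
  expect_equal(nrow(det$centroids), 0)
})

test_that("three separated spots are found within 1 px of truth", {
  set.seed(21)
  truth_pos <- rbind(c(10, 12), c(25, 40), c(38, 20))
  img <- spiketrack:::add_gaussian_spots_cpp(matrix(0, 50, 55), truth_pos,
                                             rep(50, 3), 2)
  img <- img + matrix(rnorm(50 * 55), 50, 55)
  det <- detect_wavelet(pmax(img, 0), wavelet_params(2, 3))
  expect_equal(nrow(det$centroids), 3)
  d <- spiketrack:::cross_dist(det$centroids, truth_pos)
  expect_true(all(apply(d, 2, min) < 1))
})

test_that("components below the minimum area are filtered out", {
  img <- matrix(0, 40, 40)
  img[20, 20] <- 40                       # single-pixel speck
  img[8:12, 8:12] <- 30                   # large block survives
  lax <- detect_wavelet(img, wavelet_params(1, 2, min_area_px = 1))
  speck <- lax$areas[apply(lax$centroids, 1,
                           function(p) sqrt(sum((p - c(19, 19))^2)) < 3)]
  expect_true(length(speck) >= 1 && all(speck < 5))
  strict <- detect_wavelet(img, wavelet_params(1, 2, min_area_px = 5))
  expect_true(all(strict$areas >= 5))
  expect_false(any(apply(strict$centroids, 1,
                         function(p) sqrt(sum((p - c(19, 19))^2)) < 3)))
})

test_that("perfect predictions score precision = recall = f1 = 1", {
  d <- frame_detections(0, rbind(c(5, 5), c(10, 10)), c(6, 6))
  m <- evaluate_detections(d, d, 2)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)
})

test_that("the published wavelet confusion counts give f1 = 72.0%", {
  m <- detection_metrics(tp = 2171, fp = 576, fn = 1112,
                         distance_threshold_d = 1)
  expect_equal(round(100 * m$f1, 1), 72.0)
  expect_equal(m$n_pred, 2747)
})

test_that("matching beats greedy and equals the exhaustive optimum", {
  # greedy would pair the first pred with the nearer truth and lose the
  # second match; optimal one-to-one matching keeps both
  pred <- frame_detections(0, rbind(c(0, 0), c(0, 1.2)), c(5, 5))
  truth <- frame_detections(0, rbind(c(0, 0.7), c(0, 2.0)), c(5, 5))
  m <- evaluate_detections(pred, truth, 1.5)
  expect_equal(m$tp, 2)
  # exhaustive oracle over both one-to-one matchings
  d <- spiketrack:::cross_dist(pred$centroids, truth$centroids)
  best_tp <- max(sum(c(d[1, 1], d[2, 2]) < 1.5),
                 sum(c(d[1, 2], d[2, 1]) < 1.5))
  expect_equal(m$tp, best_tp)
})

test_that("evaluate_detections is symmetric with precision/recall swapped", {
  set.seed(3)
  a <- frame_detections(0, matrix(runif(20, 0, 30), 10), rep(5, 10))
  b <- frame_detections(0, matrix(runif(14, 0, 30), 7), rep(5, 7))
  m1 <- evaluate_detections(a, b, 4)
  m2 <- evaluate_detections(b, a, 4)
  expect_equal(m1$tp, m2$tp)
  expect_equal(m1$precision, m2$recall)
  expect_equal(m1$recall, m2$precision)
})

test_that("raising k_sigma never increases the detection count", {
  sim <- fix_sim_sparse()
  img <- sim$anchor$frames[1, , ]
  counts <- vapply(c(1, 2, 3, 4, 6), function(k)
    nrow(detect_wavelet(img, wavelet_params(2, k))$centroids), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("calibration returns the exhaustive argmax with tie-breaks", {
  sim <- fix_sim_sparse()
  train <- lapply(0:1, function(t)
    list(frame = sim$anchor$frames[t + 1, , ],
         truth = truth_detections(sim$truth, t)))
  scales <- c(1, 2); ks <- c(2, 3)
  best <- calibrate_wavelet(train, scales, ks, d = 2)
  # exhaustive oracle
  grid <- expand.grid(scale = scales, k_sigma = ks)
  grid$f1 <- vapply(seq_len(nrow(grid)), function(g) {
    p <- wavelet_params(grid$scale[g], grid$k_sigma[g])
    mean(vapply(train, function(ti)
      evaluate_detections(detect_wavelet(ti$frame, p), ti$truth, 2)$f1,
      0.0))
  }, 0.0)
  expect_equal(attr(best, "mean_f1"), max(grid$f1))
  # tie-break: duplicate grid values must return the smallest scale/k
  single <- calibrate_wavelet(train, 2, 3, d = 2)
  expect_equal(single$scale, 2L)
  expect_equal(single$k_sigma, 3)
  tied <- calibrate_wavelet(train, c(best$scale, best$scale),
                            c(best$k_sigma, best$k_sigma), d = 2)
  expect_equal(tied$scale, best$scale)
  expect_equal(tied$k_sigma, best$k_sigma)
  expect_error(calibrate_wavelet(train, numeric(0), 3, 2), "empty")
})
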
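# Non-neuronal filtering, ICA artifact removal, detrending, smoothing.
# Frozen oracle values below were computed with scipy 1.17 (signal.butter,
# signal.filtfilt, stats.normaltest) on the exact inputs used here.

test_that("Butterworth design matches the reference coefficients", {
  co <- butter_highpass(5, 0.02)
  expect_equal(co$b,
               c(0.9033142753351562, -4.516571376675781, 9.033142753351562,
                 -9.033142753351562, 4.516571376675781,
                 -0.9033142753351562), tolerance = 1e-12)
  expect_equal(co$a,
               c(1.0, -4.796681599817806, 9.20724237509201,
                 -8.84036968250099, 4.245786473289919,
                 -0.8159766800242779), tolerance = 1e-12)
})

test_that("zero-phase filtering matches the reference implementation", {
  co <- butter_highpass(5, 0.02)
  t <- 0:199
  x <- sin(2 * pi * t / 100) + sin(2 * pi * t / 10)
  y <- filtfilt(co$b, co$a, x)
  expect_lt(abs(y[1] - -0.34562995480063474), 1e-8)
  expect_lt(abs(y[51] - 0.09470928562723746), 1e-8)
  expect_lt(abs(y[101] - -0.0038660607616960614), 1e-8)
  expect_lt(abs(sum(y^2) - 114.80015675504312), 1e-6)
})

test_that("the omnibus normality test matches the reference values", {
  r1 <- dagostino_pearson_test(sin(1:100))
  expect_equal(r1$statistic, 234.8519089520248, tolerance = 1e-9)
  expect_equal(r1$p_value, 1.0059026188899914e-51, tolerance = 1e-6)
  v2 <- c(rep(0, 90), rep(5, 10)) + 0.1 * sin(1:100)
  r2 <- dagostino_pearson_test(v2)
  expect_equal(r2$statistic, 69.125642537711, tolerance = 1e-9)
  expect_error(dagostino_pearson_test(rnorm(10)), "at least 20")
})

mk_signals <- function(cal, ctl = NULL) {
  TT <- length(cal)
  if (is.null(ctl)) ctl <- rep(1, TT)
  neuron_signals(1, 0, TT - 1, ctl, cal, matrix(0, TT, 2))
}

test_that("noise-like and constant traces are flagged non-neuronal", {
  set.seed(33)
  p <- signal_proc_params()
  gauss <- classify_non_neuronal(list(mk_signals(rnorm(400))), p)
  expect_false(gauss$keep_flag)
  expect_gt(gauss$p_value, 0.05)

  spiky <- rnorm(400) * 0.3
  g <- c(1.6678, -0.6816)
  s <- numeric(400); s[seq(30, 390, by = 40)] <- 1
  spiky <- spiky + 5 * as.numeric(stats::filter(s, g, method = "recursive"))
  trans <- classify_non_neuronal(list(mk_signals(spiky)), p)
  expect_true(trans$keep_flag)

  flat <- classify_non_neuronal(list(mk_signals(rep(2, 400))), p)
  expect_false(flat$keep_flag)
  expect_equal(flat$p_value, 1)
})

test_that("ICA with a degenerate constant control returns the calcium", {
  p <- signal_proc_params()
  cal <- sin(1:300) + 2
  out <- ica_motion_correct(cal, rep(5, 300), p)
  expect_equal(as.numeric(out), cal)
})

test_that("ICA separates an exact shared artifact from the calcium", {
  set.seed(34)
  p <- signal_proc_params()
  g <- c(1.6678, -0.6816)
  s <- numeric(600); s[sample(600, 8)] <- 1
  cal_true <- as.numeric(stats::filter(s, g, method = "recursive"))
  artifact <- numeric(600)
  for (a0 in c(100, 250, 400)) artifact[a0:(a0 + 8)] <- -3
  green <- cal_true + artifact
  red <- artifact + 0.01 * rnorm(600)
  out <- ica_motion_correct(green, red, p)
  expect_gte(abs(cor(out, cal_true)), 0.99)
  expect_gt(cor(out, cal_true), cor(green, cal_true))  # it actually helped
  # determinism under the fixed seed in params
  out2 <- ica_motion_correct(green, red, p)
  expect_identical(as.numeric(out), as.numeric(out2))
  # length and missing-value mask preserved
  g2 <- c(NA, green, NA)
  r2 <- c(NA, red, NA)
  out3 <- ica_motion_correct(g2, r2, p)
  expect_length(out3, 602)
  expect_true(is.na(out3[1]) && is.na(out3[602]))
})

test_that("detrending removes DC and slow drift, keeps fast transients", {
  p <- signal_proc_params()
  expect_lt(max(abs(detrend_trace(rep(7, 500), p))), 1e-8)

  tt <- 0:999
  bleach <- 10 * exp(-tt / 500)
  slow_out <- detrend_trace(bleach, p)
  # bleach amplitude (peak-to-peak) attenuated > 90%
  expect_lt(diff(range(slow_out)) / diff(range(bleach)), 0.1)
  # FFT-gain oracle at the transient's characteristic frequency (a
  # 20-frame period probe): retained > 70%
  fast <- sin(2 * pi * tt / 20)
  fast_out <- detrend_trace(fast, p)
  expect_gt(sqrt(mean(fast_out[300:700]^2) / mean(fast[300:700]^2)), 0.7)

  # cutoff definition: a sinusoid at the critical period passes each
  # filtering direction with |H| = 1/sqrt(2) (half power per pass)
  xs <- sin(2 * pi * tt / 100)
  ys <- detrend_trace(xs, p)
  gain <- sqrt(mean(ys[300:700]^2) / mean(xs[300:700]^2))
  expect_equal(gain, 0.5, tolerance = 0.05)

  expect_error(detrend_trace(rep(1, 10), p), "warm-up|short")
})

test_that("detrending is idempotent within 1% energy", {
  set.seed(35)
  p <- signal_proc_params()
  # broadband traces; signals with most energy right at the cutoff can be
  # re-attenuated by up to ~1% of their energy on a second pass
  for (rep in 1:3) {
    x <- rnorm(800)
    y1 <- detrend_trace(x, p)
    y2 <- detrend_trace(y1, p)
    i <- 50:750
    expect_lt(sum((y2[i] - y1[i])^2) / sum(y1[i]^2), 0.01)
  }
})

test_that("rolling average: identity on constants, impulse, variance law", {
  p <- signal_proc_params()
  expect_equal(smooth_trace(rep(3, 20), p), rep(3, 20))
  imp <- numeric(21); imp[11] <- 1
  sm <- smooth_trace(imp, p)
  expect_equal(sm[9:13], rep(0.2, 5))
  expect_equal(sum(sm), 1)
  set.seed(36)
  x <- rnorm(5000)
  sm <- smooth_trace(x, p)
  expect_equal(sd(sm[10:4990]), 1 / sqrt(5), tolerance = 0.1)
  # shrinking edge windows: first sample is the mean of the first 3
  expect_equal(smooth_trace(c(1, 2, 3, 4, 5, 6, 7), p)[1], 2)
})

test_that("stages preserve length and the missing-frame mask", {
  p <- signal_proc_params()
  x <- c(rep(NA, 5), sin(1:300) + 2, rep(NA, 3))
  for (f in list(function(v) detrend_trace(v, p),
                 function(v) smooth_trace(v, p))) {
    y <- f(x)
    expect_length(y, length(x))
    expect_identical(is.na(y), is.na(x))
  }
  expect_error(detrend_trace(c(1, NA, 3, 4), p), "interior missing")
})
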
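# Trace-level signal processing: non-neuronal (plateau) cell filtering via
# a normality test, shared-channel motion-artifact removal with two-signal
# ICA, zero-phase Butterworth detrending, and rolling-average smoothing.
# The stage order is fixed: raw -> ICA -> detrend -> smooth.

#' Signal processing parameters
#'
#' @param normality_p_threshold cells whose calcium trace is *not*
#'   distinguishable from Gaussian noise at this level are flagged
#'   non-neuronal (default 0.05).
#' @param ica_runs number of ICA restarts (default 10).
#' @param ica_tolerance FastICA convergence tolerance (default 0.5).
#' @param butter_order high-pass Butterworth order (default 5).
#' @param critical_period_frames detrending cutoff period in frames
#'   (default 100): slower fluctuations are removed.
#' @param smooth_window_frames rolling-average window (odd, default 5).
#' @param rng_seed seed for the stochastic ICA restarts.
#' @return an object of class `signal_proc_params`.
#' @export
signal_proc_params <- function(normality_p_threshold = 0.05, ica_runs = 10,
                               ica_tolerance = 0.5, butter_order = 5,
                               critical_period_frames = 100,
                               smooth_window_frames = 5, rng_seed = 1) {
  stopifnot(normality_p_threshold > 0, normality_p_threshold < 1,
            ica_runs >= 1, butter_order >= 1,
            smooth_window_frames >= 1, smooth_window_frames %% 2 == 1,
            critical_period_frames > 2 * smooth_window_frames)
  structure(as.list(environment()), class = "signal_proc_params")
}

# ---- contiguous-span helpers -------------------------------------------

trace_span <- function(x) {
  ok <- which(!is.na(x))
  if (!length(ok)) stopf("trace is entirely missing")
  if (!identical(ok, ok[1]:ok[length(ok)]))
    stopf("trace has interior missing values")
  ok
}

apply_to_span <- function(x, fun) {
  idx <- trace_span(x)
  out <- rep(NA_real_, length(x))
  out[idx] <- fun(x[idx])
  out
}

# ---- D'Agostino-Pearson omnibus normality test --------------------------

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness and kurtosis into
#' `K2 = Z1^2 + Z2^2`, referred to a chi-squared distribution with 2
#' degrees of freedom.
#'
#' @param x numeric vector, length >= 20.
#' @return list with `statistic` and `p_value`.
#' @export
dagostino_pearson_test <- function(x) {
  n <- length(x)
  if (n < 20) stopf("normality test requires at least 20 observations")
  x <- x - mean(x)
  m2 <- mean(x^2); m3 <- mean(x^3); m4 <- mean(x^4)
  if (m2 <= 0) stopf("zero-variance input")
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  # skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transform (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - eb2) / sqrt(vb2)  # non-excess kurtosis enters here
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  denom <- 1 + xk * sqrt(2 / (a - 4))
  term2 <- sign(denom) * ((1 - 2 / a) / abs(denom))^(1 / 3)
  z2 <- ((1 - 2 / (9 * a)) - term2) * sqrt(9 * a / 2)
  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Flag non-neuronal (plateau / noise-like) cells
#'
#' Applies the omnibus normality test to each mean-subtracted raw calcium
#' trace. Traces whose normality is rejected (`p < threshold`) look like
#' spiking neurons and are kept; Gaussian-looking traces (activated
#' plateau cells whose residual variation is imaging noise, e.g.
#' nematocytes) are flagged for removal. Zero-variance traces are flagged
#' with `p` reported as 1. The report replaces an interactive review step:
#' override flags via the pipeline config allow/deny lists.
#'
#' @param signals list of [neuron_signals()].
#' @param params a [signal_proc_params()].
#' @return data.frame with `track_id`, `p_value`, `keep_flag`.
#' @export
classify_non_neuronal <- function(signals, params) {
  rows <- lapply(signals, function(s) {
    x <- s$calcium_raw[trace_span(s$calcium_raw)]
    # traces too short for a valid test, or flat, are flagged non-neuronal
    p <- if (length(x) < 20 || is.na(sd(x)) || sd(x) == 0) 1
         else dagostino_pearson_test(x - mean(x))$p_value
    data.frame(track_id = s$track_id, p_value = p,
               keep_flag = p < params$normality_p_threshold)
  })
  do.call(rbind, rows)
}

# ---- two-signal FastICA -------------------------------------------------

# symmetric FastICA (logcosh nonlinearity) specialised to 2 sources
fastica2 <- function(X, tol = 1e-4, max_iter = 200) {
  Xc <- sweep(X, 2, colMeans(X))
  C <- stats::cov(Xc)
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < 1e-12 * max(ev$values))
    return(list(S = NULL, converged = FALSE))
  Kw <- ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  Z <- Xc %*% Kw
  W <- matrix(rnorm(4), 2, 2)
  sym_decorr <- function(W) {
    sv <- eigen(W %*% t(W), symmetric = TRUE)
    solve_sqrt <- sv$vectors %*% diag(1 / sqrt(pmax(sv$values, 1e-12))) %*%
      t(sv$vectors)
    solve_sqrt %*% W
  }
  W <- sym_decorr(W)
  n <- nrow(Z)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W)
    G <- tanh(WX)
    Gp <- 1 - G^2
    W1 <- t(G) %*% Z / n - diag(colMeans(Gp)) %*% W
    W1 <- sym_decorr(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  list(S = Z %*% t(W), converged = converged)
}

#' Remove shared-channel motion artifacts with ICA
#'
#' Runs 2-component ICA on the standardized (calcium, control) pair several
#' times with different random starts. In each run the calcium component is
#' the output more correlated (in absolute value) with the raw calcium
#' trace; across runs the component least correlated with the control
#' signal wins. The winner is sign-fixed to correlate positively with the
#' raw calcium and rescaled to its mean and variance. If no run converges
#' the raw calcium is returned with a `warning` attribute.
#'
#' @param calcium_raw,control equal-length traces (NA only outside the
#'   common covered span).
#' @param params a [signal_proc_params()].
#' @return motion-corrected calcium trace (same length, same NA mask).
#' @export
ica_motion_correct <- function(calcium_raw, control, params) {
  idx <- trace_span(calcium_raw)
  if (!identical(idx, trace_span(control)))
    stopf("calcium and control traces cover different spans")
  cal <- calcium_raw[idx]; ctl <- control[idx]
  m <- mean(cal); s <- sd(cal)
  if (s == 0 || sd(ctl) == 0) {
    out <- calcium_raw
    attr(out, "warning") <- "degenerate input; ICA skipped"
    return(out)
  }
  zc <- (cal - m) / s
  zr <- (ctl - mean(ctl)) / sd(ctl)
  best <- NULL; best_score <- Inf
  for (run in seq_len(params$ica_runs)) {
    set.seed(derive_seed(params$rng_seed, run))
    res <- fastica2(cbind(zc, zr), tol = params$ica_tolerance)
    if (is.null(res$S) || !res$converged) next
    cors_cal <- abs(cor(res$S, zc))
    comp <- res$S[, which.max(cors_cal)]
    score <- abs(cor(comp, zr))
    if (score < best_score) { best_score <- score; best <- comp }
  }
  out <- rep(NA_real_, length(calcium_raw))
  if (is.null(best)) {
    out <- calcium_raw
    attr(out, "warning") <- "ICA did not converge in any run"
    return(out)
  }
  best <- best * sign(cor(best, zc))
  best <- (best - mean(best)) / sd(best)
  out[idx] <- m + s * best
  out
}

# ---- Butterworth design and zero-phase filtering ------------------------

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, rt * p)
  p
}

#' Butterworth high-pass filter coefficients
#'
#' Digital Butterworth design via the bilinear transform; `wn` is the
#' cutoff as a fraction of the Nyquist frequency (as in common DSP
#' toolboxes).
#'
#' @param order filter order.
#' @param wn normalized cutoff in (0, 1).
#' @return list with numerator `b` and denominator `a`.
#' @export
butter_highpass <- function(order, wn) {
  stopifnot(order >= 1, wn > 0, wn < 1)
  k <- seq_len(order)
  # analog low-pass prototype poles on the unit circle (left half-plane)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  fs <- 2
  warped <- 2 * fs * tan(pi * wn / fs)
  # low-pass -> high-pass: poles warped/p, n zeros at s = 0
  ph <- warped / p
  # bilinear transform; the n analog zeros at s = 0 map to z = 1 (DC block)
  fs2 <- 2 * fs
  pz <- (fs2 + ph) / (fs2 - ph)
  zz <- rep(1 + 0i, order)
  kz <- Re(fs2^order / prod(fs2 - ph))
  b <- Re(poly_from_roots(zz)) * kz
  a <- Re(poly_from_roots(pz))
  list(b = b, a = a)
}

# direct-form-II-transposed IIR filter with optional initial conditions
iir_filter <- function(b, a, x, zi = NULL) {
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b))) / a[1]
  a <- c(a, rep(0, nfilt - length(a))) / a[1]
  z <- if (is.null(zi)) rep(0, nfilt - 1) else zi
  y <- numeric(length(x))
  bt <- b[-1]; at <- a[-1]
  for (mi in seq_along(x)) {
    xm <- x[mi]
    ym <- b[1] * xm + z[1]
    z <- c(z[-1], 0) + bt * xm - at * ym
    y[mi] <- ym
  }
  y
}

# steady-state initial conditions for a unit step (scipy lfilter_zi)
lfilter_zi <- function(b, a) {
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b))) / a[1]
  a <- c(a, rep(0, nfilt - length(a))) / a[1]
  n <- nfilt - 1
  comp <- rbind(-a[2:nfilt], cbind(diag(1, n - 1), rep(0, n - 1)))
  IminusA <- diag(1, n) - t(comp)
  B <- b[2:nfilt] - a[2:nfilt] * b[1]
  as.numeric(solve(IminusA, B))
}

#' Zero-phase forward-backward filtering
#'
#' Applies the filter forward and backward with odd-reflection padding and
#' steady-state initial conditions, cancelling the phase response (so spike
#' times are not shifted).
#'
#' @param b,a filter coefficients.
#' @param x input trace.
#' @return filtered trace of the same length.
#' @export
filtfilt <- function(b, a, x) {
  nfilt <- max(length(a), length(b))
  edge <- 3L * nfilt
  n <- length(x)
  if (n <= edge) stopf("trace too short to filter (need > %d samples)", edge)
  ext <- c(2 * x[1] - x[(edge + 1):2], x, 2 * x[n] - x[(n - 1):(n - edge)])
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(edge + 1):(edge + n)]
}

#' Detrend a trace with a zero-phase high-pass Butterworth filter
#'
#' Removes fluctuations slower than `critical_period_frames` (cutoff
#' frequency `1/critical_period` cycles per frame), e.g. photobleaching
#' baselines, while preserving transient timing.
#'
#' @param x trace (NA allowed outside the covered span).
#' @param params a [signal_proc_params()].
#' @return detrended trace with mean ~0 on the covered span.
#' @export
detrend_trace <- function(x, params) {
  co <- butter_highpass(params$butter_order,
                        2 / params$critical_period_frames)
  apply_to_span(x, function(v) {
    if (length(v) <= 3 * params$butter_order + 1)
      stopf("trace shorter than the filter warm-up (%d samples)",
            3 * params$butter_order + 1)
    filtfilt(co$b, co$a, v)
  })
}

#' Rolling-average smoothing
#'
#' Centred moving average; edge windows shrink (no invented padding).
#'
#' @param x trace (NA allowed outside the covered span).
#' @param params a [signal_proc_params()] (uses `smooth_window_frames`).
#' @return smoothed trace.
#' @export
smooth_trace <- function(x, params) {
  w <- params$smooth_window_frames
  h <- (w - 1L) %/% 2L
  apply_to_span(x, function(v) {
    n <- length(v)
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
}
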
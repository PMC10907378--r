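#' @useDynLib spiketrack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats mad filter fft pchisq rnorm runif rbinom rpois sd cor
#'   quantile optim setNames
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' One-dimensional Gaussian kernel
#'
#' @param sigma standard deviation in samples.
#' @param truncate kernel half-width in units of `sigma`.
#' @return numeric vector of odd length summing to 1.
#' @keywords internal
gaussian_kernel1d <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  h <- max(1L, as.integer(ceiling(truncate * sigma)))
  x <- (-h):h
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# pad a vector by reflection (scipy 'reflect': edge value not repeated)
pad_reflect <- function(x, h) {
  n <- length(x)
  if (h == 0) return(x)
  left <- x[pmin(n, pmax(1, (h + 1):2))]
  right <- x[pmax(1, pmin(n, (n - 1):(n - h)))]
  c(left, x, right)
}

# 1-D convolution, 'same' size, reflect padding
conv1d_reflect <- function(x, k) {
  h <- (length(k) - 1L) %/% 2L
  xp <- pad_reflect(x, h)
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(h + 1L):(h + length(x))])
}

# 1-D convolution, 'same' size, zero padding (for spike trains: no events
# outside the recorded span)
conv1d_zero <- function(x, k) {
  h <- (length(k) - 1L) %/% 2L
  xp <- c(rep(0, h), x, rep(0, h))
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(h + 1L):(h + length(x))])
}

# separable 2-D Gaussian blur with reflect padding (shift-and-add)
gaussian_blur2d <- function(img, sigma, truncate = 4) {
  if (sigma <= 0) return(img)
  conv_sep(img, gaussian_kernel1d(sigma, truncate))
}

# mean image intensity over the disc of given radius centred at the
# (possibly sub-pixel) position (r0, c0); pixels included iff their centre
# lies within the Euclidean radius; out-of-bounds pixels are dropped
disc_mean <- function(img, r0, c0, radius) {
  H <- nrow(img); W <- ncol(img)
  rr <- max(0L, floor(r0 - radius)):min(H - 1L, ceiling(r0 + radius))
  cc <- max(0L, floor(c0 - radius)):min(W - 1L, ceiling(c0 + radius))
  if (rr[1] > rr[length(rr)] || cc[1] > cc[length(cc)]) return(NA_real_)
  nr <- length(rr); nc <- length(cc)
  gr <- rep(rr, nc); gc <- rep(cc, each = nr)
  keep <- (gr - r0)^2 + (gc - c0)^2 <= radius^2
  if (!any(keep)) return(NA_real_)
  mean(img[gr[keep] + 1L + gc[keep] * H])
}

# deterministic per-purpose seed derived from a base seed (kept < 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

# pairwise Euclidean distance matrix between two n x 2 / m x 2 point sets
cross_dist <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(a, ncol = 2)
  if (!is.matrix(b)) b <- matrix(b, ncol = 2)
  dr <- outer(a[, 1], b[, 1], "-")
  dc <- outer(a[, 2], b[, 2], "-")
  sqrt(dr * dr + dc * dc)
}
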
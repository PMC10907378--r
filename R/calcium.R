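# Linking tracked nuclei (anchor channel) to cell bodies in the misaligned
# activity channel. A small ROI around each tracked nucleus is searched for
# prior-weighted local maxima; across frames the maximum closest to the
# previous calcium position is followed with an exponential moving average,
# and signals are read out as disc means at the tracked positions.

#' Sub-ROI linking parameters
#'
#' Defaults follow the standard recipe: a 25 x 25 px ROI, 5 iterated local
#' maxima, Gaussian smoothing with sigma 1 px, a Gaussian positional prior
#' with sigma 5 px centred on the nucleus, and disc read-out of radius 5 px.
#'
#' @param roi_size_px odd ROI side length.
#' @param n_maxima number of candidate maxima extracted per ROI.
#' @param smooth_sigma_px Gaussian smoothing sigma before peak search.
#' @param prior_sigma_px sigma of the Gaussian prior centred on the nucleus.
#' @param extract_radius_px disc radius for intensity read-out.
#' @param ema_rate exponential-moving-average rate in (0, 1]; 0.5 halves the
#'   influence of any single wrong association.
#' @param suppression_radius_px disc radius zeroed around each found
#'   maximum before the next iteration.
#' @return an object of class `subroi_params`.
#' @export
subroi_params <- function(roi_size_px = 25, n_maxima = 5,
                          smooth_sigma_px = 1, prior_sigma_px = 5,
                          extract_radius_px = 5, ema_rate = 0.5,
                          suppression_radius_px = 3) {
  if (roi_size_px %% 2 == 0) stopf("roi_size_px must be odd")
  if (roi_size_px < 2 * extract_radius_px + 1)
    stopf("roi_size_px must be at least 2*extract_radius_px + 1")
  stopifnot(n_maxima >= 1, ema_rate > 0, ema_rate <= 1)
  structure(list(roi_size_px = as.integer(roi_size_px),
                 n_maxima = as.integer(n_maxima),
                 smooth_sigma_px = smooth_sigma_px,
                 prior_sigma_px = prior_sigma_px,
                 extract_radius_px = extract_radius_px,
                 ema_rate = ema_rate,
                 suppression_radius_px = suppression_radius_px),
            class = "subroi_params")
}

# extract a roi_size x roi_size patch centred on the rounded position,
# replicating edge pixels; returns the patch plus the image coordinates of
# each patch row/column
extract_roi <- function(img, center, size) {
  half <- (size - 1L) %/% 2L
  r0 <- as.integer(round(center[1])); c0 <- as.integer(round(center[2]))
  ridx <- pmin(pmax((r0 - half):(r0 + half), 0L), nrow(img) - 1L)
  cidx <- pmin(pmax((c0 - half):(c0 + half), 0L), ncol(img) - 1L)
  list(patch = img[ridx + 1L, cidx + 1L, drop = FALSE],
       rows = ridx, cols = cidx)
}

#' Find prior-weighted local maxima within an ROI
#'
#' The patch is Gaussian-smoothed, multiplied by a Gaussian prior centred
#' on the patch centre, and the global maximum is extracted `n_maxima`
#' times, zeroing a suppression disc around each hit.
#'
#' @param roi square numeric patch.
#' @param params a [subroi_params()].
#' @return n x 2 matrix of 0-based (row, col) patch coordinates, in
#'   decreasing order of weighted intensity.
#' @export
find_roi_maxima <- function(roi, params) {
  H <- nrow(roi); W <- ncol(roi)
  sm <- gaussian_blur2d(roi, params$smooth_sigma_px)
  weighted <- sm * prior_weights(H, W, params$prior_sigma_px)
  out <- matrix(NA_real_, 0, 2)
  wts <- numeric(0)
  rad2 <- params$suppression_radius_px^2
  for (k in seq_len(params$n_maxima)) {
    idx <- which.max(weighted)
    if (!is.finite(weighted[idx])) break
    wts <- c(wts, weighted[idx])
    r <- (idx - 1L) %% H; c <- (idx - 1L) %/% H
    # the prior ranks and selects candidates but shrinks their position
    # toward the patch centre; refine with a local centre of mass of the
    # prior-free smoothed patch, bounded by the suppression radius so the
    # refinement cannot wander onto a neighbouring cell body
    out <- rbind(out, local_com(sm, r, c, params$suppression_radius_px))
    d2 <- outer((0:(H - 1) - r)^2, (0:(W - 1) - c)^2, "+")
    weighted[d2 <= rad2] <- -Inf
    if (all(weighted == -Inf)) break
  }
  attr(out, "weights") <- wts  # prior-weighted brightness of each candidate
  out
}

# memoised centred Gaussian prior for a given patch geometry
prior_cache <- new.env(parent = emptyenv())
prior_weights <- function(H, W, sigma) {
  key <- sprintf("%d_%d_%g", H, W, sigma)
  if (is.null(prior_cache[[key]])) {
    ctr <- c((H - 1) / 2, (W - 1) / 2)
    pr <- outer((0:(H - 1) - ctr[1])^2, (0:(W - 1) - ctr[2])^2, "+")
    prior_cache[[key]] <- exp(-pr / (2 * sigma^2))
  }
  prior_cache[[key]]
}

# intensity-weighted centre of mass of img over the disc of given radius
# around (r, c); the disc minimum is subtracted so the estimate tracks the
# local peak rather than the patch baseline
local_com <- function(img, r, c, radius) {
  H <- nrow(img); W <- ncol(img)
  rr <- max(0L, r - radius):min(H - 1L, r + radius)
  cc <- max(0L, c - radius):min(W - 1L, c + radius)
  gr <- rep(rr, length(cc)); gc <- rep(cc, each = length(rr))
  keep <- (gr - r)^2 + (gc - c)^2 <= radius^2
  gr <- gr[keep]; gc <- gc[keep]
  w <- img[gr + 1L + gc * H]
  w <- w - min(w)
  if (sum(w) <= 0) return(c(r, c))
  c(sum(w * gr), sum(w * gc)) / sum(w)
}

#' Track a neuron's calcium position in the activity channel
#'
#' Frame 1 of the track uses the global prior-weighted maximum of the ROI.
#' On subsequent frames each candidate maximum is scored by its
#' prior-weighted brightness (brightness times proximity to the nucleus)
#' times its proximity to the previous calcium position (Gaussian in the
#' distance, same sigma as the nucleus prior); the best-scoring candidate
#' is blended in with an exponential moving average:
#' `pos <- (1 - ema_rate) * pos + ema_rate * candidate`. Weighting
#' brightness, centre proximity and previous-position proximity together
#' keeps the tracked position on the correct cell body even while an
#' equally bright neighbour inside the ROI is firing.
#'
#' @param tr a [track()].
#' @param activity the activity-channel [movie()].
#' @param params a [subroi_params()].
#' @return matrix (span x 2) of (row, col) calcium positions, one per
#'   covered frame.
#' @export
track_calcium_positions <- function(tr, activity, params) {
  TT <- n_frames(activity)
  if (tr$start_frame < 0 || tr$end_frame > TT - 1)
    stopf("track %d extends outside the movie", tr$track_id)
  span <- track_frames(tr)
  out <- matrix(NA_real_, length(span), 2)
  prev <- NULL
  for (k in seq_along(span)) {
    f <- span[k]
    nuc <- tr$positions[k, ]
    roi <- extract_roi(frame_of(activity, f), nuc, params$roi_size_px)
    mx <- find_roi_maxima(roi$patch, params)
    # map (possibly fractional) patch coordinates to image coordinates
    fr <- pmin(pmax(floor(mx[, 1]), 0), length(roi$rows) - 1L)
    fc <- pmin(pmax(floor(mx[, 2]), 0), length(roi$cols) - 1L)
    cand <- cbind(roi$rows[fr + 1L] + (mx[, 1] - fr),
                  roi$cols[fc + 1L] + (mx[, 2] - fc))
    if (is.null(prev)) {
      prev <- cand[1, ]
    } else {
      d2 <- (cand[, 1] - prev[1])^2 + (cand[, 2] - prev[2])^2
      w <- attr(mx, "weights")
      score <- w * exp(-d2 / (2 * params$prior_sigma_px^2))
      sel <- cand[which.max(score), ]
      prev <- (1 - params$ema_rate) * prev + params$ema_rate * sel
    }
    out[k, ] <- prev
  }
  out
}

#' Extract per-neuron control and calcium traces
#'
#' `control[t]` is the mean anchor-channel intensity over the disc of
#' `extract_radius_px` centred on the nucleus position; `calcium_raw[t]`
#' the mean activity-channel intensity over the same-radius disc at the
#' tracked calcium position. Discs clipped at the image border use only
#' in-bounds pixels. Frames outside the track span are `NA`.
#'
#' @param tr a [track()].
#' @param anchor,activity the two [movie()] channels.
#' @param params a [subroi_params()].
#' @return a [neuron_signals()].
#' @export
extract_signals <- function(tr, anchor, activity, params) {
  TT <- n_frames(anchor)
  if (n_frames(activity) != TT)
    stopf("channel movies differ in length")
  if (tr$start_frame < 0 || tr$end_frame > TT - 1)
    stopf("track %d extends outside the movie", tr$track_id)
  cal_pos_span <- track_calcium_positions(tr, activity, params)
  control <- rep(NA_real_, TT)
  calcium_raw <- rep(NA_real_, TT)
  cal_pos <- matrix(NA_real_, TT, 2)
  span <- track_frames(tr)
  for (k in seq_along(span)) {
    f <- span[k]
    control[f + 1L] <- disc_mean(frame_of(anchor, f), tr$positions[k, 1],
                                 tr$positions[k, 2],
                                 params$extract_radius_px)
    calcium_raw[f + 1L] <- disc_mean(frame_of(activity, f),
                                     cal_pos_span[k, 1], cal_pos_span[k, 2],
                                     params$extract_radius_px)
    cal_pos[f + 1L, ] <- cal_pos_span[k, ]
  }
  neuron_signals(tr$track_id, tr$start_frame, tr$end_frame, control,
                 calcium_raw, cal_pos)
}
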
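# Tracklet stitching: undetected positions are propagated forward from
# tracklet ends (and backward from tracklet starts) through per-frame-step
# thin-plate-spline deformations fitted to the tracklets that are detected
# on both sides of the step. The pairwise stitch cost is the minimal
# distance between the forward and backward estimates, and the global
# linking is a linear assignment solved with the Jonker-Volgenant
# algorithm; chains of linked tracklets merge into full tracks.

#' Stitching parameters
#'
#' @param alpha thin-plate-spline smoothness (default 10, enough
#'   regularization to be robust to upstream linking errors).
#' @param eta_px non-linking cost in pixels (default 5): the total price of
#'   leaving a tracklet unstitched, so links form only when the propagation
#'   distance is below `eta_px`.
#' @param max_gap_frames maximal temporal gap bridged (default 50).
#' @param min_neighbors minimal number of control tracklets for a TPS step
#'   (default 4); propagation truncates where fewer are available.
#' @return an object of class `stitch_params`.
#' @export
stitch_params <- function(alpha = 10, eta_px = 5, max_gap_frames = 50,
                          min_neighbors = 4) {
  stopifnot(alpha >= 0, eta_px > 0, max_gap_frames >= 1, min_neighbors >= 3)
  structure(list(alpha = alpha, eta_px = eta_px,
                 max_gap_frames = as.integer(max_gap_frames),
                 min_neighbors = as.integer(min_neighbors)),
            class = "stitch_params")
}

#' Fit a smoothed thin-plate-spline deformation
#'
#' Minimizes squared residuals plus `alpha` times the bending energy. The
#' affine part is unpenalized: any affine map (in particular a pure
#' translation) is reproduced exactly for every `alpha`.
#'
#' @param source,target n x 2 matrices of (row, col) control points.
#' @param alpha smoothness (0 interpolates).
#' @return an object of class `tps_map`; apply with [tps_apply()].
#' @export
tps_fit <- function(source, target, alpha = 0) {
  if (!is.matrix(source)) source <- matrix(source, ncol = 2)
  if (!is.matrix(target)) target <- matrix(target, ncol = 2)
  n <- nrow(source)
  if (n < 3) stopf("need at least 3 control points")
  ctr <- sweep(source, 2, colMeans(source))
  sv <- svd(ctr)$d
  if (sv[2] < 1e-8 * max(sv[1], 1e-12))
    stopf(paste("degenerate (collinear or coincident) control points;",
                "fall back to an affine fit"))
  K <- tps_kernel(cross_dist(source, source))
  P <- cbind(1, source)
  A <- rbind(cbind(K + diag(alpha, n), P),
             cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(target, matrix(0, 3, 2))
  sol <- solve(A, rhs)
  structure(list(source = source, w = sol[1:n, , drop = FALSE],
                 a = sol[(n + 1):(n + 3), , drop = FALSE]),
            class = "tps_map")
}

tps_kernel <- function(r) {
  u <- r * r * log(r)
  u[!is.finite(u)] <- 0
  u
}

#' Apply a fitted TPS map to points
#'
#' @param map a `tps_map` from [tps_fit()].
#' @param x m x 2 matrix of (row, col) points.
#' @return m x 2 matrix of mapped points.
#' @export
tps_apply <- function(map, x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 2)
  U <- tps_kernel(cross_dist(x, map$source))
  U %*% map$w + cbind(1, x) %*% map$a
}

# control points for the deformation across the frame step t -> t + dir:
# positions of tracklets DETECTED at both frames
step_controls <- function(tracklets, t, dir) {
  src <- list(); dst <- list()
  for (tr in tracklets) {
    p1 <- track_position(tr, t)
    p2 <- track_position(tr, t + dir)
    if (anyNA(p1) || anyNA(p2)) next
    s1 <- tr$status[t - tr$start_frame + 1L]
    s2 <- tr$status[t + dir - tr$start_frame + 1L]
    if (s1 != "DETECTED" || s2 != "DETECTED") next
    src[[length(src) + 1L]] <- p1
    dst[[length(dst) + 1L]] <- p2
  }
  if (!length(src)) return(NULL)
  list(src = do.call(rbind, src), dst = do.call(rbind, dst))
}

# shared cache of per-step TPS maps; dir = +1 forward, -1 backward
make_step_mapper <- function(tracklets, params) {
  cache <- new.env(parent = emptyenv())
  function(t, dir) {
    key <- sprintf("%d_%d", t, dir)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ctl <- step_controls(tracklets, t, dir)
    res <- if (is.null(ctl) || nrow(ctl$src) < params$min_neighbors) {
      "truncated"
    } else {
      tryCatch(tps_fit(ctl$src, ctl$dst, params$alpha),
               error = function(e) "truncated")
    }
    cache[[key]] <- res
    res
  }
}

#' Propagate a tracklet's position beyond its span
#'
#' After a tracklet ends, its position is advanced one frame at a time by
#' the TPS deformation fitted between consecutive frames from all tracklets
#' detected at both (forward propagation); [propagate_backward()] runs the
#' same scheme time-reversed from the tracklet's start.
#'
#' @param tracklet the [track()] to propagate.
#' @param tracklets all tracklets of the movie (control-point source).
#' @param params a [stitch_params()].
#' @param n_frames number of frames to propagate.
#' @param n_total total frame count of the movie.
#' @param mapper optional shared step-map cache (internal).
#' @return matrix with columns `frame, row, col`; the first row is the
#'   tracklet's own terminal position. Propagation stops early (recorded by
#'   simply ending) where fewer than `min_neighbors` controls exist.
#' @export
propagate_forward <- function(tracklet, tracklets, params, n_frames,
                              n_total = Inf, mapper = NULL) {
  propagate_dir(tracklet, tracklets, params, n_frames, n_total, +1L, mapper)
}

#' @rdname propagate_forward
#' @export
propagate_backward <- function(tracklet, tracklets, params, n_frames,
                               n_total = Inf, mapper = NULL) {
  propagate_dir(tracklet, tracklets, params, n_frames, n_total, -1L, mapper)
}

propagate_dir <- function(tracklet, tracklets, params, n_frames, n_total,
                          dir, mapper = NULL) {
  if (is.null(mapper)) mapper <- make_step_mapper(tracklets, params)
  t0 <- if (dir > 0) tracklet$end_frame else tracklet$start_frame
  pos <- track_position(tracklet, t0)
  out <- matrix(c(t0, pos), 1, 3,
                dimnames = list(NULL, c("frame", "row", "col")))
  t <- t0
  for (step in seq_len(n_frames)) {
    tn <- t + dir
    if (tn < 0 || tn > n_total - 1) break
    map <- mapper(t, dir)
    if (identical(map, "truncated")) break
    pos <- as.numeric(tps_apply(map, matrix(pos, 1, 2)))
    out <- rbind(out, c(tn, pos))
    t <- tn
  }
  out
}

#' Build the tracklet stitch cost matrix
#'
#' `cost[i, j]` is the minimal Euclidean distance between tracklet `i`'s
#' forward-propagated and tracklet `j`'s backward-propagated positions over
#' the frames both estimates cover; it is infinite unless `j` starts
#' strictly after `i` ends within `max_gap_frames`, or if the propagations
#' never overlap (e.g. both truncated).
#'
#' @param tracklets list of [track()] objects from one movie.
#' @param params a [stitch_params()].
#' @return list with `costs` (N x N matrix), `tracklet_ids`, and the
#'   cached propagations `fwd` and `bwd`.
#' @export
build_stitch_costs <- function(tracklets, params) {
  N <- length(tracklets)
  n_total <- if (N) max(vapply(tracklets, function(x) x$end_frame, 0L)) + 1L
             else 0L
  mapper <- make_step_mapper(tracklets, params)
  fwd <- lapply(tracklets, propagate_forward, tracklets = tracklets,
                params = params, n_frames = params$max_gap_frames,
                n_total = n_total, mapper = mapper)
  bwd <- lapply(tracklets, propagate_backward, tracklets = tracklets,
                params = params, n_frames = params$max_gap_frames,
                n_total = n_total, mapper = mapper)
  costs <- matrix(Inf, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i == j) next
      gap <- tracklets[[j]]$start_frame - tracklets[[i]]$end_frame
      if (gap < 1 || gap > params$max_gap_frames) next
      fi <- fwd[[i]]; bj <- bwd[[j]]
      common <- intersect(fi[, "frame"], bj[, "frame"])
      if (!length(common)) next
      d <- vapply(common, function(f) {
        euclid(fi[fi[, "frame"] == f, 2:3], bj[bj[, "frame"] == f, 2:3])
      }, 0.0)
      costs[i, j] <- min(d)
    }
  }
  list(costs = costs,
       tracklet_ids = vapply(tracklets, function(x) x$track_id, 0L),
       fwd = fwd, bwd = bwd)
}

#' Stitch tracklets into full tracks
#'
#' Solves the linear assignment problem in which linking tracklet `i` to
#' `j` pays `cost[i, j]` and leaving an endpoint unlinked pays `eta_px / 2`
#' (so an isolated tracklet pays `eta_px` in total, and a link forms only
#' when its cost is below `eta_px`). Chains of linked tracklets merge into
#' single tracks whose gap frames are filled with blended
#' forward/backward-propagated positions flagged `INTERPOLATED`.
#'
#' @param tracklets list of [track()] objects.
#' @param params a [stitch_params()].
#' @return list of [track()] objects; each has `parent_tracklets` recording
#'   the merged tracklet ids, and the attribute `links` gives the accepted
#'   (i, j) index pairs.
#' @export
stitch <- function(tracklets, params) {
  N <- length(tracklets)
  if (N == 0L) return(list())
  cm <- build_stitch_costs(tracklets, params)
  links <- solve_link_assignment(cm$costs, params$eta_px)

  succ <- rep(NA_integer_, N)
  pred <- rep(NA_integer_, N)
  if (nrow(links)) {
    succ[links[, 1]] <- links[, 2]
    pred[links[, 2]] <- links[, 1]
  }
  heads <- which(is.na(pred))
  out <- list()
  for (h in heads) {
    chain <- h
    while (!is.na(succ[chain[length(chain)]]))
      chain <- c(chain, succ[chain[length(chain)]])
    out[[length(out) + 1L]] <- merge_chain(tracklets, chain, cm)
  }
  for (k in seq_along(out)) out[[k]]$track_id <- k
  attr(out, "links") <- links
  out
}

# assignment with per-endpoint non-link cost eta/2 (see stitch())
solve_link_assignment <- function(costs, eta_px) {
  N <- nrow(costs)
  m <- 2L * N
  big <- matrix(Inf, m, m)
  big[1:N, 1:N] <- costs
  for (k in 1:N) {
    big[k, N + k] <- eta_px / 2
    big[N + k, k] <- eta_px / 2
  }
  big[(N + 1):m, (N + 1):m] <- 0
  sol <- lap_solve_cpp(big)
  links <- matrix(0L, 0, 2, dimnames = list(NULL, c("from", "to")))
  for (i in 1:N) {
    j <- sol$assignment[i]
    if (j <= N && is.finite(costs[i, j]))
      links <- rbind(links, c(i, j))
  }
  links
}

merge_chain <- function(tracklets, chain, cm) {
  if (length(chain) == 1L) {
    tr <- tracklets[[chain]]
    tr$parent_tracklets <- tr$track_id
    return(tr)
  }
  first <- tracklets[[chain[1]]]
  start <- first$start_frame
  end <- tracklets[[chain[length(chain)]]]$end_frame
  n <- end - start + 1L
  positions <- matrix(NA_real_, n, 2)
  status <- rep("INTERPOLATED", n)
  for (ci in chain) {
    tr <- tracklets[[ci]]
    idx <- (tr$start_frame:tr$end_frame) - start + 1L
    positions[idx, ] <- tr$positions
    status[idx] <- tr$status
  }
  # fill gaps with blended forward/backward propagation
  for (k in seq_len(length(chain) - 1L)) {
    i <- chain[k]; j <- chain[k + 1L]
    e <- tracklets[[i]]$end_frame; s <- tracklets[[j]]$start_frame
    if (s - e <= 1L) next
    fi <- cm$fwd[[i]]; bj <- cm$bwd[[j]]
    pe <- tracklets[[i]]$positions[nrow(tracklets[[i]]$positions), ]
    ps <- tracklets[[j]]$positions[1, ]
    for (f in (e + 1L):(s - 1L)) {
      w <- (f - e) / (s - e)
      pf <- fi[fi[, "frame"] == f, 2:3]
      pb <- bj[bj[, "frame"] == f, 2:3]
      pos <- if (length(pf) && length(pb)) (1 - w) * pf + w * pb
             else if (length(pf)) pf
             else if (length(pb)) pb
             else (1 - w) * pe + w * ps
      positions[f - start + 1L, ] <- pos
    }
  }
  track(first$track_id, start, positions, status = status,
        parent_tracklets = vapply(tracklets[chain],
                                  function(x) x$track_id, 0L))
}
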
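# Conservative frame-to-frame tracklet generation: per-track constant
# velocity Kalman prediction, gated distances to the current detections,
# and a min-cost one-to-one assignment per frame. This fills the role a
# probabilistic multi-hypothesis tracker plays in production pipelines,
# behind the same contract (detections in, tracklets out), and is
# deliberately pluggable.

#' Tracklet linker parameters
#'
#' @param gate_radius_px maximal admissible per-frame displacement.
#' @param max_missed_frames consecutive undetected frames a track may coast
#'   before termination (default 5, the typical gap after which
#'   frame-to-frame trackers give up and identities must be re-stitched).
#' @param process_noise white-acceleration s.d. of the constant-velocity
#'   model (px/frame^2).
#' @param measurement_noise detection noise s.d. (px).
#' @return an object of class `linker_params`.
#' @export
linker_params <- function(gate_radius_px, max_missed_frames = 5,
                          process_noise = 1, measurement_noise = 1) {
  stopifnot(gate_radius_px > 0, max_missed_frames >= 0,
            process_noise > 0, measurement_noise > 0)
  structure(list(gate_radius_px = gate_radius_px,
                 max_missed_frames = as.integer(max_missed_frames),
                 process_noise = process_noise,
                 measurement_noise = measurement_noise),
            class = "linker_params")
}

KF_F <- matrix(c(1, 0, 0, 0,
                 0, 1, 0, 0,
                 1, 0, 1, 0,
                 0, 1, 0, 1), 4, 4)  # column-major: x' = F %*% x
KF_H <- matrix(c(1, 0, 0, 1, 0, 0, 0, 0), 2, 4)

kf_Q <- function(q) {
  q^2 * matrix(c(0.25, 0, 0.5, 0,
                 0, 0.25, 0, 0.5,
                 0.5, 0, 1, 0,
                 0, 0.5, 0, 1), 4, 4)
}

#' Link detections into tracklets
#'
#' Per frame, every live track's position is predicted with its
#' constant-velocity Kalman state; a cost matrix of predicted-to-detected
#' distances (gated at `gate_radius_px` Euclidean, or by the Mahalanobis
#' distance for uncertain coasting tracks) is solved as a min-cost
#' one-to-one assignment. Unmatched tracks coast up to `max_missed_frames`
#' and are then terminated with the coasted tail trimmed back to the last
#' detected frame; interior coasted frames (track re-acquired) keep their
#' predicted positions flagged `INTERPOLATED`. Unmatched detections seed
#' new tracks with zero initial velocity and inflated covariance.
#'
#' @param detections list of [frame_detections()] ordered by frame.
#' @param params a [linker_params()].
#' @return list of [track()] tracklets.
#' @export
link_detections <- function(detections, params) {
  stopifnot(inherits(params, "linker_params"))
  r2 <- params$measurement_noise^2
  Q <- kf_Q(params$process_noise)
  Rm <- diag(r2, 2)
  active <- list()
  done <- list()
  next_id <- 0L

  finalize <- function(tr) {
    det <- tr$status == "DETECTED"
    if (!any(det)) return(NULL)
    last <- max(which(det))
    first <- min(which(det))
    idx <- first:last
    track(tr$id, tr$start_frame + first - 1L,
          do.call(rbind, tr$positions[idx]), status = tr$status[idx])
  }

  for (di in seq_along(detections)) {
    det <- detections[[di]]
    tf <- det$frame_index
    D <- det$centroids
    nd <- nrow(D)

    # predict
    for (k in seq_along(active)) {
      a <- active[[k]]
      a$x <- KF_F %*% a$x
      a$P <- KF_F %*% a$P %*% t(KF_F) + Q
      active[[k]] <- a
    }
    nt <- length(active)

    matched_t <- rep(FALSE, nt); matched_d <- rep(FALSE, nd)
    assign_td <- integer(nt)
    if (nt > 0L && nd > 0L) {
      preds <- t(vapply(active, function(a) as.numeric(KF_H %*% a$x),
                        numeric(2)))
      cost <- cross_dist(preds, D)
      adm <- cost <= params$gate_radius_px
      # widen the gate with predictive uncertainty for coasting tracks
      for (k in seq_len(nt)) {
        if (all(adm[k, ])) next
        S <- KF_H %*% active[[k]]$P %*% t(KF_H) + Rm
        Sinv <- solve(S)
        dv <- sweep(D, 2, preds[k, ])
        maha2 <- rowSums((dv %*% Sinv) * dv)
        adm[k, ] <- adm[k, ] | maha2 <= 9
      }
      kappa <- params$gate_radius_px + 1
      m <- nt + nd
      big <- matrix(Inf, m, m)
      cfull <- cost; cfull[!adm] <- Inf
      big[1:nt, 1:nd] <- cfull
      for (k in seq_len(nt)) big[k, nd + k] <- kappa
      for (k in seq_len(nd)) big[nt + k, k] <- kappa
      big[(nt + 1):m, (nd + 1):m] <- 0
      sol <- lap_solve_cpp(big)
      for (k in seq_len(nt)) {
        j <- sol$assignment[k]
        if (j <= nd && is.finite(cfull[k, j])) {
          matched_t[k] <- TRUE; matched_d[j] <- TRUE; assign_td[k] <- j
        }
      }
    }

    keep <- logical(length(active))
    for (k in seq_along(active)) {
      a <- active[[k]]
      if (matched_t[k]) {
        z <- D[assign_td[k], ]
        S <- KF_H %*% a$P %*% t(KF_H) + Rm
        K <- a$P %*% t(KF_H) %*% solve(S)
        a$x <- a$x + K %*% (z - KF_H %*% a$x)
        a$P <- (diag(4) - K %*% KF_H) %*% a$P
        a$positions <- c(a$positions, list(z))
        a$status <- c(a$status, "DETECTED")
        a$missed <- 0L
        keep[k] <- TRUE
      } else {
        a$missed <- a$missed + 1L
        if (a$missed > params$max_missed_frames) {
          tr <- finalize(a)
          if (!is.null(tr)) done[[length(done) + 1L]] <- tr
          keep[k] <- FALSE
        } else {
          a$positions <- c(a$positions, list(as.numeric(KF_H %*% a$x)))
          a$status <- c(a$status, "INTERPOLATED")
          keep[k] <- TRUE
        }
      }
      active[[k]] <- a
    }
    active <- active[keep]

    if (nd > 0L) for (j in which(!matched_d)) {
      next_id <- next_id + 1L
      active[[length(active) + 1L]] <-
        list(id = next_id, start_frame = tf,
             x = matrix(c(D[j, ], 0, 0), 4, 1),
             P = diag(c(r2, r2, 100 * r2, 100 * r2)),
             positions = list(D[j, ]), status = "DETECTED", missed = 0L)
    }
  }

  for (a in active) {
    tr <- finalize(a)
    if (!is.null(tr)) done[[length(done) + 1L]] <- tr
  }
  done[order(vapply(done, function(x) x$track_id, 0L))]
}
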
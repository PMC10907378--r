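# Core domain types and their plain-text serializations.
#
# Coordinate convention, used everywhere in the package: 0-based (row, col)
# with the origin at the top-left pixel and pixel centers at integer
# coordinates. Frames are indexed 0-based as well.

#' Construct a single-channel movie
#'
#' A movie is a T x H x W array of non-negative finite intensities in
#' arbitrary camera units, with an acquisition rate and a channel label.
#'
#' @param frames T x H x W numeric array, or a list of H x W matrices.
#' @param frame_rate_hz acquisition rate in frames per second (default 10,
#'   the rate needed to keep up with the fastest body contractions).
#' @param channel_name `"anchor"` (calcium-insensitive nuclear label used
#'   for tracking) or `"activity"` (cytoplasmic calcium indicator).
#' @return an object of class `movie`.
#' @export
movie <- function(frames, frame_rate_hz = 10,
                  channel_name = c("anchor", "activity")) {
  channel_name <- match.arg(channel_name)
  if (is.list(frames)) {
    shape <- dim(frames[[1]])
    arr <- array(NA_real_, c(length(frames), shape))
    for (t in seq_along(frames)) {
      if (!identical(dim(frames[[t]]), shape))
        stopf("frame %d has shape %s, expected %s", t,
              paste(dim(frames[[t]]), collapse = "x"),
              paste(shape, collapse = "x"))
      arr[t, , ] <- frames[[t]]
    }
    frames <- arr
  }
  if (length(dim(frames)) != 3L) stopf("frames must be a T x H x W array")
  if (dim(frames)[1] < 1L) stopf("movie must have at least one frame")
  if (!all(is.finite(frames))) stopf("movie intensities must be finite")
  if (any(frames < 0)) stopf("movie intensities must be non-negative")
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stopf("frame_rate_hz must be positive")
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 channel_name = channel_name,
                 cache = new.env(parent = emptyenv())),
            class = "movie")
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie> channel=%s  T=%d  %dx%d px  %.3g fps\n",
              x$channel_name, d[1], d[2], d[3], x$frame_rate_hz))
  invisible(x)
}

n_frames <- function(m) dim(m$frames)[1]

# 0-based frame access; slicing the first index of a T x H x W array is a
# strided gather, so frames are materialised once per movie and cached
frame_of <- function(m, t) {
  cache <- m$cache
  if (is.null(cache)) return(m$frames[t + 1L, , ])
  if (is.null(cache$fl))
    cache$fl <- lapply(seq_len(dim(m$frames)[1]),
                       function(k) m$frames[k, , ])
  cache$fl[[t + 1L]]
}

#' Read a movie from a multi-page TIFF
#'
#' @inheritParams movie
#' @param path path to a grayscale multi-page TIFF.
#' @return a [movie()] with `T` equal to the page count; intensities are
#'   promoted to double precision.
#' @export
read_movie <- function(path, frame_rate_hz = 10,
                       channel_name = c("anchor", "activity")) {
  movie(read_tiff_stack(path), frame_rate_hz = frame_rate_hz,
        channel_name = match.arg(channel_name))
}

#' Write a movie to a multi-page TIFF
#'
#' @param m a [movie()].
#' @param path output path.
#' @param dtype passed to [write_tiff_stack()]; the default `"float64"`
#'   makes write/read round-trips exact.
#' @export
write_movie <- function(m, path, dtype = "float64") {
  write_tiff_stack(m$frames, path, dtype = dtype)
}

#' Per-frame nucleus detections
#'
#' @param frame_index 0-based frame index.
#' @param centroids n x 2 matrix of (row, col) center-of-mass coordinates.
#' @param areas integer vector of component pixel counts (same length).
#' @param label_mask optional H x W integer label image.
#' @return an object of class `frame_detections`.
#' @export
frame_detections <- function(frame_index, centroids, areas,
                             label_mask = NULL) {
  if (is.null(centroids)) centroids <- matrix(numeric(0), ncol = 2)
  if (!is.matrix(centroids)) centroids <- matrix(centroids, ncol = 2)
  if (nrow(centroids) != length(areas))
    stopf("centroids and areas disagree in length")
  colnames(centroids) <- c("row", "col")
  structure(list(frame_index = as.integer(frame_index),
                 centroids = centroids, areas = as.numeric(areas),
                 label_mask = label_mask),
            class = "frame_detections")
}

#' Write / read per-frame detections as CSV
#'
#' Columns: `frame, row, col, area`.
#'
#' @param detections list of [frame_detections()].
#' @param path CSV path.
#' @export
write_detections_csv <- function(detections, path) {
  rows <- lapply(detections, function(d) {
    if (nrow(d$centroids) == 0L) return(NULL)
    data.frame(frame = d$frame_index, row = d$centroids[, 1],
               col = d$centroids[, 2], area = d$areas)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(frame = integer(0), row = numeric(0),
                     col = numeric(0), area = numeric(0))
  write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @param n_frames total number of frames (frames with no detections are
#'   returned as empty `frame_detections`); defaults to `max(frame) + 1`.
#' @export
read_detections_csv <- function(path, n_frames = NULL) {
  df <- read.csv(path)
  if (is.null(n_frames))
    n_frames <- if (nrow(df)) max(df$frame) + 1L else 0L
  lapply(seq_len(n_frames) - 1L, function(t) {
    sub <- df[df$frame == t, , drop = FALSE]
    frame_detections(t, cbind(sub$row, sub$col), sub$area)
  })
}

#' Construct a track
#'
#' A track is one putative cell identity covering the contiguous frame span
#' `[start_frame, end_frame]` (0-based, inclusive), with a per-frame
#' position and a per-frame status: `"DETECTED"` where a detection was
#' assigned, `"INTERPOLATED"` where the position was filled in (stitching
#' gaps, interior coasting).
#'
#' @param track_id integer identity.
#' @param start_frame,end_frame 0-based inclusive frame span.
#' @param positions n x 2 (row, col) matrix, `n = end - start + 1`.
#' @param status character vector of the same length.
#' @param parent_tracklets ids of tracklets merged into this track.
#' @return an object of class `track`.
#' @export
track <- function(track_id, start_frame, positions,
                  status = rep("DETECTED", nrow(positions)),
                  parent_tracklets = integer(0),
                  end_frame = start_frame + nrow(positions) - 1L) {
  if (!is.matrix(positions)) positions <- matrix(positions, ncol = 2)
  n <- nrow(positions)
  if (n != end_frame - start_frame + 1L)
    stopf("track %s: %d positions for span [%d, %d]", track_id, n,
          start_frame, end_frame)
  if (length(status) != n) stopf("track %s: status length mismatch", track_id)
  if (any(!is.finite(positions)))
    stopf("track %s: undefined positions inside its span", track_id)
  if (!all(status %in% c("DETECTED", "INTERPOLATED")))
    stopf("track %s: invalid status values", track_id)
  colnames(positions) <- c("row", "col")
  structure(list(track_id = as.integer(track_id),
                 start_frame = as.integer(start_frame),
                 end_frame = as.integer(end_frame),
                 positions = positions, status = status,
                 parent_tracklets = as.integer(parent_tracklets)),
            class = "track")
}

track_frames <- function(tr) tr$start_frame:tr$end_frame

# position of a track at a 0-based frame, or c(NA, NA) outside its span
track_position <- function(tr, t) {
  if (t < tr$start_frame || t > tr$end_frame) return(c(NA_real_, NA_real_))
  tr$positions[t - tr$start_frame + 1L, ]
}

#' Write / read tracks as CSV
#'
#' Columns: exactly `track_id, frame, row, col, status`, one row per covered
#' frame. The round-trip is lossless to 6 decimal places. Duplicate
#' `(track_id, frame)` rows on read raise a format error.
#'
#' @param tracks list of [track()] objects.
#' @param path CSV path.
#' @export
write_tracks_csv <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    data.frame(track_id = tr$track_id, frame = track_frames(tr),
               row = tr$positions[, 1], col = tr$positions[, 2],
               status = tr$status)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(track_id = integer(0), frame = integer(0),
                     row = numeric(0), col = numeric(0),
                     status = character(0))
  write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- read.csv(path, colClasses = c(status = "character"))
  need <- c("track_id", "frame", "row", "col", "status")
  if (!identical(names(df), need))
    stopf("tracks CSV must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(df[c("track_id", "frame")]))
    stopf("tracks CSV contains duplicate (track_id, frame) rows")
  lapply(split(df, df$track_id), function(sub) {
    sub <- sub[order(sub$frame), ]
    if (!identical(sub$frame, seq(min(sub$frame), max(sub$frame))))
      stopf("track %d has non-contiguous frames", sub$track_id[1])
    track(sub$track_id[1], min(sub$frame), cbind(sub$row, sub$col),
          status = sub$status)
  })
}

# fixed-precision numeric formatting shared by the CSV writers
format_num_df <- function(df) {
  for (k in names(df))
    if (is.double(df[[k]])) df[[k]] <- sprintf("%.6f", df[[k]])
  df
}

#' Per-neuron extracted and processed signals
#'
#' All traces have the full movie length `T`; frames outside the owning
#' track's span are `NA` (an explicit missing marker -- 0 is a legal
#' intensity and is never used as a sentinel).
#'
#' @param track_id owning track id.
#' @param start_frame,end_frame covered span (0-based, inclusive).
#' @param control anchor-channel mean-intensity trace (length `T`).
#' @param calcium_raw raw activity-channel trace (length `T`).
#' @param calcium_positions `T` x 2 matrix of per-frame activity-channel
#'   positions.
#' @param calcium_ica,calcium_detrended,calcium_smoothed processed stages,
#'   `NULL` until computed.
#' @return an object of class `neuron_signals`.
#' @export
neuron_signals <- function(track_id, start_frame, end_frame, control,
                           calcium_raw, calcium_positions,
                           calcium_ica = NULL, calcium_detrended = NULL,
                           calcium_smoothed = NULL) {
  TT <- length(control)
  traces <- list(control = control, calcium_raw = calcium_raw,
                 calcium_ica = calcium_ica,
                 calcium_detrended = calcium_detrended,
                 calcium_smoothed = calcium_smoothed)
  span <- (start_frame:end_frame) + 1L
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    if (is.null(tr)) next
    if (length(tr) != TT)
      stopf("trace %s has length %d, expected %d", nm, length(tr), TT)
    if (anyNA(tr[span]))
      stopf("trace %s is missing inside the covered span", nm)
  }
  structure(c(list(track_id = as.integer(track_id),
                   start_frame = as.integer(start_frame),
                   end_frame = as.integer(end_frame),
                   calcium_positions = calcium_positions),
              traces),
            class = "neuron_signals")
}

#' Write / read per-neuron traces as CSV
#'
#' Wide format with one column per processing stage:
#' `track_id, frame, control, calcium_raw, calcium_ica,
#' calcium_detrended, calcium_smoothed` (missing stages/frames are `NA`).
#'
#' @param signals list of [neuron_signals()].
#' @param path CSV path.
#' @export
write_traces_csv <- function(signals, path) {
  stages <- c("control", "calcium_raw", "calcium_ica",
              "calcium_detrended", "calcium_smoothed")
  rows <- lapply(signals, function(s) {
    TT <- length(s$control)
    df <- data.frame(track_id = s$track_id, frame = seq_len(TT) - 1L)
    for (st in stages) df[[st]] <- s[[st]] %||% rep(NA_real_, TT)
    df
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(track_id = integer(0), frame = integer(0))
    for (st in stages) df[[st]] <- numeric(0)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Spike raster
#'
#' @param events data.frame with columns `track_id, frame, amplitude`;
#'   duplicate `(track_id, frame)` events are merged with summed amplitude.
#' @param n_neurons,n_frames raster dimensions.
#' @return an object of class `spike_raster`.
#' @export
spike_raster <- function(events, n_neurons, n_frames) {
  if (nrow(events)) {
    if (any(events$frame < 0 | events$frame >= n_frames))
      stopf("raster events outside the movie span")
    if (any(events$amplitude <= 0))
      stopf("raster amplitudes must be positive")
    agg <- stats::aggregate(amplitude ~ track_id + frame, events, sum)
    events <- agg[order(agg$track_id, agg$frame), ]
    rownames(events) <- NULL
  }
  structure(list(events = events, n_neurons = as.integer(n_neurons),
                 n_frames = as.integer(n_frames)),
            class = "spike_raster")
}

#' Write / read a spike raster as CSV
#'
#' Columns: `track_id, frame, amplitude`. Raster dimensions are stored in a
#' `# n_neurons= n_frames=` comment line.
#'
#' @param raster a [spike_raster()].
#' @param path CSV path.
#' @export
write_raster_csv <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_neurons=%d n_frames=%d", raster$n_neurons,
                     raster$n_frames), con)
  write.csv(raster$events, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header,
                  regexec("n_neurons=(\\d+) n_frames=(\\d+)", header))[[1]]
  if (length(m) != 3L) stopf("raster CSV lacks the dimension header")
  df <- read.csv(path, comment.char = "#")
  spike_raster(df, as.integer(m[2]), as.integer(m[3]))
}

#' Plot a spike raster
#'
#' @param x a [spike_raster()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.spike_raster <- function(x, ...) {
  neurons <- sort(unique(x$events$track_id))
  ypos <- match(x$events$track_id, neurons)
  graphics::plot(NA, xlim = c(0, x$n_frames), ylim = c(0, length(neurons) + 1),
                 xlab = "frame", ylab = "neuron", yaxt = "n", ...)
  if (length(neurons))
    graphics::axis(2, at = seq_along(neurons), labels = neurons, las = 1,
                   cex.axis = 0.6)
  if (nrow(x$events))
    graphics::segments(x$events$frame, ypos - 0.4, x$events$frame,
                       ypos + 0.4)
  invisible(x)
}
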
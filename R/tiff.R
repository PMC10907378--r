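# Minimal multi-page grayscale TIFF support.
#
# The imaging rigs targeted here write plain striped, uncompressed,
# single-sample TIFF stacks, and no TIFF package ships with the runtime this
# package targets, so a small baseline reader/writer is included. Supported:
# little- and big-endian, bit depths 8/16 (unsigned int) and 32/64 (IEEE
# float), any strip layout, no compression, no tiles.

TIFF_TYPE_SIZES <- c(`1` = 1L, `3` = 2L, `4` = 4L)  # BYTE, SHORT, LONG

read_tiff_ifd_values <- function(con, entry, endian) {
  # entry: list(tag, type, count, raw4) where raw4 is the 4-byte value field
  size <- TIFF_TYPE_SIZES[as.character(entry$type)]
  if (is.na(size)) return(NULL)
  nbytes <- size * entry$count
  sgn <- size >= 4L  # readBin only supports unsigned for 1- and 2-byte ints
  if (nbytes <= 4L) {
    vals <- readBin(entry$raw4, "integer", n = entry$count, size = size,
                    signed = sgn, endian = endian)
  } else {
    offset <- readBin(entry$raw4, "integer", n = 1L, size = 4L,
                      endian = endian)
    old <- seek(con, where = NA)
    seek(con, offset)
    vals <- readBin(con, "integer", n = entry$count, size = size,
                    signed = sgn, endian = endian)
    seek(con, old)
  }
  vals
}

#' Read a multi-page grayscale TIFF stack
#'
#' @param path path to an uncompressed striped grayscale TIFF.
#' @return list of numeric H x W matrices, one per page.
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stopf("TIFF file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  byte_order <- readChar(con, 2, useBytes = TRUE)
  endian <- switch(byte_order, II = "little", MM = "big",
                   stopf("not a TIFF file (bad byte-order mark): %s", path))
  magic <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  if (magic != 42L) stopf("not a TIFF file (magic != 42): %s", path)
  ifd_offset <- readBin(con, "integer", 1L, size = 4L, endian = endian)

  pages <- list()
  page_no <- 0L
  shape0 <- NULL
  while (ifd_offset != 0L) {
    page_no <- page_no + 1L
    seek(con, ifd_offset)
    n_entries <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                         endian = endian)
    entries <- vector("list", n_entries)
    for (i in seq_len(n_entries)) {
      tag <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                     endian = endian)
      type <- readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                      endian = endian)
      count <- readBin(con, "integer", 1L, size = 4L, endian = endian)
      raw4 <- readBin(con, "raw", 4L)
      entries[[i]] <- list(tag = tag, type = type, count = count,
                           raw4 = raw4)
    }
    ifd_offset <- readBin(con, "integer", 1L, size = 4L, endian = endian)

    tags <- vapply(entries, `[[`, 0L, "tag")
    getv <- function(tag, default = NULL) {
      k <- match(tag, tags)
      if (is.na(k)) return(default)
      read_tiff_ifd_values(con, entries[[k]], endian)
    }
    W <- getv(256L); H <- getv(257L)
    if (is.null(W) || is.null(H))
      stopf("TIFF page %d lacks image dimensions", page_no)
    bits <- getv(258L, 1L)[1]
    compression <- getv(259L, 1L)[1]
    if (compression != 1L)
      stopf("TIFF page %d uses compression %d; only uncompressed supported",
            page_no, compression)
    if (!is.null(getv(322L)))
      stopf("TIFF page %d is tiled; only strips supported", page_no)
    spp <- getv(277L, 1L)[1]
    if (spp != 1L)
      stopf("TIFF page %d has %d samples/pixel; only grayscale supported",
            page_no, spp)
    fmt <- getv(339L, 1L)[1]
    offsets <- getv(273L)
    counts <- getv(279L)
    if (is.null(offsets) || is.null(counts))
      stopf("TIFF page %d lacks strip layout tags", page_no)

    raw <- raw(0)
    for (k in seq_along(offsets)) {
      seek(con, offsets[k])
      raw <- c(raw, readBin(con, "raw", counts[k]))
    }
    n_px <- as.numeric(H) * as.numeric(W)
    if (fmt == 3L) {
      if (!bits %in% c(32L, 64L))
        stopf("TIFF page %d: unsupported float depth %d", page_no, bits)
      vals <- readBin(raw, "numeric", n = n_px, size = bits %/% 8L,
                      endian = endian)
    } else if (fmt %in% c(1L, NA)) {
      if (!bits %in% c(8L, 16L))
        stopf("TIFF page %d: unsupported integer depth %d", page_no, bits)
      vals <- readBin(raw, "integer", n = n_px, size = bits %/% 8L,
                      signed = FALSE, endian = endian)
      vals <- as.numeric(vals)
    } else {
      stopf("TIFF page %d: unsupported sample format %d", page_no, fmt)
    }
    if (length(vals) < n_px)
      stopf("TIFF page %d: truncated pixel data", page_no)
    frame <- t(matrix(vals, nrow = W, ncol = H))  # stored row-major
    if (is.null(shape0)) shape0 <- dim(frame)
    if (!identical(dim(frame), shape0))
      stopf("TIFF page %d has shape %dx%d, expected %dx%d", page_no,
            nrow(frame), ncol(frame), shape0[1], shape0[2])
    pages[[page_no]] <- frame
  }
  if (page_no == 0L) stopf("TIFF file has no pages: %s", path)
  pages
}

write_tiff_entry <- function(con, tag, type, count, value) {
  writeBin(as.integer(tag), con, size = 2L, endian = "little")
  writeBin(as.integer(type), con, size = 2L, endian = "little")
  writeBin(as.integer(count), con, size = 4L, endian = "little")
  writeBin(as.integer(value), con, size = 4L, endian = "little")
}

#' Write a multi-page grayscale TIFF stack
#'
#' @param frames list of numeric H x W matrices (all the same shape).
#' @param path output path.
#' @param dtype sample encoding; `"float64"` (default, lossless for R
#'   doubles), `"float32"`, `"uint16"` or `"uint8"`.
#' @export
write_tiff_stack <- function(frames, path,
                             dtype = c("float64", "float32", "uint16",
                                       "uint8")) {
  dtype <- match.arg(dtype)
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[1]), function(t) frames[t, , ])
  stopifnot(length(frames) >= 1L)
  shape <- dim(frames[[1]])
  H <- shape[1]; W <- shape[2]
  for (k in seq_along(frames))
    if (!identical(dim(frames[[k]]), shape))
      stopf("frame %d has a different shape", k)
  bits <- switch(dtype, float64 = 64L, float32 = 32L, uint16 = 16L,
                 uint8 = 8L)
  fmt <- if (startsWith(dtype, "float")) 3L else 1L
  bytes_per_px <- bits %/% 8L
  n_pages <- length(frames)
  strip_bytes <- H * W * bytes_per_px

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL, useBytes = TRUE)
  writeBin(42L, con, size = 2L, endian = "little")
  data_start <- 8L
  ifd_start <- data_start + n_pages * strip_bytes
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  writeBin(as.integer(ifd_start), con, size = 4L, endian = "little")

  for (k in seq_len(n_pages)) {
    v <- as.vector(t(frames[[k]]))  # row-major
    if (fmt == 1L) {
      v <- as.integer(round(v))
      if (any(v < 0) || any(v >= 2^bits))
        stopf("frame %d out of range for %s", k, dtype)
      if (bits == 8L) writeBin(as.raw(v), con)
      else writeBin(v, con, size = 2L, endian = "little")
    } else {
      writeBin(as.numeric(v), con, size = bytes_per_px, endian = "little")
    }
  }
  for (k in seq_len(n_pages)) {
    writeBin(n_entries, con, size = 2L, endian = "little")
    write_tiff_entry(con, 256L, 4L, 1L, W)
    write_tiff_entry(con, 257L, 4L, 1L, H)
    write_tiff_entry(con, 258L, 3L, 1L, bits)
    write_tiff_entry(con, 259L, 3L, 1L, 1L)          # no compression
    write_tiff_entry(con, 262L, 3L, 1L, 1L)          # black is zero
    write_tiff_entry(con, 273L, 4L, 1L, data_start + (k - 1L) * strip_bytes)
    write_tiff_entry(con, 277L, 3L, 1L, 1L)
    write_tiff_entry(con, 278L, 4L, 1L, H)
    write_tiff_entry(con, 279L, 4L, 1L, strip_bytes)
    write_tiff_entry(con, 339L, 3L, 1L, fmt)
    nxt <- if (k < n_pages) ifd_start + k * ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4L, endian = "little")
  }
  invisible(path)
}
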
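#' Minimal baseline TIFF codec for single-plane grayscale slices
#'
#' The pipeline's on-disk interface is the simplest TIFF dialect microscope
#' exporters produce for per-slice z-stack dumps: single image, single sample
#' per pixel, 8- or 16-bit unsigned, uncompressed. No R TIFF package is
#' assumed; this codec implements exactly that dialect (and refuses anything
#' else, loudly).
#'
#' @param path file to read.
#' @return `read_tiff()`: an integer matrix (rows = image rows) with attribute
#'   `bit_depth` (8 or 16).
#' @seealso [write_tiff()]
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file (truncated): ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  u16 <- function(off) readBin(raw[(off + 1L):(off + 2L)], "integer",
                               size = 2L, signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(raw[(off + 1L):(off + 4L)], "integer", size = 4L, endian = endian)
    if (v < 0) v <- v + 2^32
    v
  }
  if (u16(2L) != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd <- u32(4L)
  n_entries <- u16(ifd)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- ifd + 2L + (i - 1L) * 12L
    tag <- u16(off); type <- u16(off + 2L); count <- u32(off + 4L)
    # inline SHORT/LONG values; otherwise an offset to the value array
    val <- if (type == 3L && count <= 2L) {
      vapply(seq_len(count), function(k) u16(off + 8L + (k - 1L) * 2L), 0L)
    } else if (type == 4L && count == 1L) {
      u32(off + 8L)
    } else if (type %in% c(3L, 4L)) {
      voff <- u32(off + 8L)
      step <- if (type == 3L) 2L else 4L
      rdr <- if (type == 3L) u16 else u32
      vapply(seq_len(count), function(k) rdr(voff + (k - 1L) * step), 0)
    } else NULL   # types we do not need (rationals etc.)
    tags[[as.character(tag)]] <- val
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", tag, " missing in ", path)
      default
    } else v
  }
  width  <- need(256L); height <- need(257L)
  bits   <- need(258L, 8L)[1L]
  comp   <- need(259L, 1L)
  spp    <- need(277L, 1L)
  if (comp != 1L) stop("unsupported TIFF compression (", comp, ") in ", path)
  if (spp != 1L) stop("only single-sample grayscale TIFF supported: ", path)
  if (!bits %in% c(8L, 16L)) stop("unsupported bit depth ", bits, " in ", path)
  offsets <- need(273L)
  counts  <- need(279L)
  bytes <- unlist(lapply(seq_along(offsets), function(i)
    raw[(offsets[i] + 1L):(offsets[i] + counts[i])]), use.names = FALSE)
  px <- readBin(bytes, "integer", n = width * height,
                size = bits %/% 8L, signed = FALSE, endian = endian)
  if (length(px) != width * height)
    stop("TIFF pixel payload has wrong length in ", path)
  m <- matrix(px, nrow = height, ncol = width, byrow = TRUE)
  attr(m, "bit_depth") <- as.integer(bits)
  m
}

#' @rdname read_tiff
#' @param plane integer matrix of non-negative intensities.
#' @param bit_depth 8 or 16.
#' @return `write_tiff()`: `path`, invisibly.
#' @export
write_tiff <- function(plane, path, bit_depth = 16L) {
  stopifnot(is.matrix(plane), bit_depth %in% c(8L, 16L))
  if (anyNA(plane) || min(plane) < 0) stop("plane must be non-negative and finite")
  maxv <- 2^bit_depth - 1
  if (max(plane) > maxv) stop("intensity exceeds ", bit_depth, "-bit range")
  h <- nrow(plane); w <- ncol(plane)
  bpp <- bit_depth %/% 8L
  data_off <- 8L
  n_bytes <- w * h * bpp
  ifd_off <- data_off + n_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(ifd_off, con, size = 4L, endian = "little")
  # pixel payload, row-major
  writeBin(as.integer(t(plane)), con, size = bpp, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    writeBin(as.integer(value), con, size = 4L, endian = "little")
  }
  tags <- list(
    list(256L, 4L, 1L, w),          # ImageWidth
    list(257L, 4L, 1L, h),          # ImageLength
    list(258L, 3L, 1L, bit_depth),  # BitsPerSample
    list(259L, 3L, 1L, 1L),         # Compression: none
    list(262L, 3L, 1L, 1L),         # Photometric: BlackIsZero
    list(273L, 4L, 1L, data_off),   # StripOffsets
    list(277L, 3L, 1L, 1L),         # SamplesPerPixel
    list(278L, 4L, 1L, h),          # RowsPerStrip: one strip
    list(279L, 4L, 1L, n_bytes)     # StripByteCounts
  )
  writeBin(length(tags), con, size = 2L, endian = "little")
  for (tg in tags) do.call(entry, tg)
  writeBin(0L, con, size = 4L, endian = "little")  # no next IFD
  invisible(path)
}
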
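# Minimal TIFF I/O for single-channel microscopy frames.
#
# No TIFF library is available in the supported dependency set, so the
# package reads and writes the small subset it needs: baseline TIFF,
# little-endian, uncompressed, single-strip, grayscale 8- or 16-bit,
# optionally multi-page (one page per time point). Compressed, tiled,
# palette or RGB files are rejected with a clear error; PNG input is out
# of scope.

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L,
               samples_per_pixel = 277L, rows_per_strip = 278L,
               strip_byte_counts = 279L)

#' Read a grayscale TIFF
#'
#' Supports uncompressed little- or big-endian baseline TIFF, 8- or
#' 16-bit, single sample per pixel, one or more pages.
#'
#' @param path file path
#' @param pixel_size um per pixel attached to the returned images
#' @return a list of [gray_image()] objects, one per page (a single-page
#'   file still yields a length-1 list)
#' @export
read_tiff_gray <- function(path, pixel_size = 0.215) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stopf("not a TIFF file: %s", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stopf("not a TIFF file: %s", path)
  rd_int <- function(off, size, n = 1L)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = size >= 4L, endian = endian)  # 4-byte offsets < 2^31
  magic <- rd_int(2, 2)
  if (magic != 42L) stopf("not a baseline TIFF: %s", path)
  ifd_off <- rd_int(4, 4)
  pages <- list()
  while (ifd_off != 0) {
    n_entries <- rd_int(ifd_off, 2)
    tags <- list()
    for (k in seq_len(n_entries)) {
      e <- ifd_off + 2 + (k - 1) * 12
      tag <- rd_int(e, 2)
      typ <- rd_int(e + 2, 2)
      cnt <- rd_int(e + 4, 4)
      sz <- c(1L, 1L, 2L, 4L, 8L)[typ]
      val_off <- e + 8
      if (sz * cnt > 4) val_off <- rd_int(e + 8, 4)
      val <- if (typ %in% c(1L, 3L, 4L)) rd_int(val_off, sz, cnt) else NA
      tags[[as.character(tag)]] <- val
    }
    gettag <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    w <- gettag(TIFF_TAGS["width"]); h <- gettag(TIFF_TAGS["height"])
    if (is.null(w) || is.null(h)) stopf("TIFF page missing dimensions")
    bits <- gettag(TIFF_TAGS["bits"], 8L)[1]
    comp <- gettag(TIFF_TAGS["compression"], 1L)
    spp <- gettag(TIFF_TAGS["samples_per_pixel"], 1L)
    if (comp != 1L) stopf("unsupported TIFF: compressed (compression = %d)", comp)
    if (spp != 1L) stopf("unsupported TIFF: %d samples per pixel", spp)
    if (!bits %in% c(8L, 16L)) stopf("unsupported TIFF: %d-bit", bits)
    offs <- gettag(TIFF_TAGS["strip_offsets"])
    cnts <- gettag(TIFF_TAGS["strip_byte_counts"])
    if (is.null(offs)) stopf("TIFF page missing strip offsets")
    data <- raw(0)
    for (s in seq_along(offs))
      data <- c(data, raw[(offs[s] + 1):(offs[s] + cnts[s])])
    vals <- readBin(data, "integer", n = w * h, size = bits / 8L,
                    signed = FALSE, endian = endian)
    px <- matrix(as.double(vals), nrow = h, ncol = w, byrow = TRUE)
    pages[[length(pages) + 1]] <- gray_image(px, pixel_size)
    next_off_pos <- ifd_off + 2 + n_entries * 12
    ifd_off <- rd_int(next_off_pos, 4)
  }
  if (!length(pages)) stopf("TIFF contains no pages: %s", path)
  pages
}

#' Write grayscale images as TIFF
#'
#' Writes uncompressed little-endian baseline TIFF, 8-bit (intensities are
#' clamped to 0..255 and rounded) or 16-bit. A list of images becomes a
#' multi-page file.
#'
#' @param images an [gray_image()] object or list of them
#' @param path file path
#' @param bits 8 or 16
#' @export
write_tiff_gray <- function(images, path, bits = 8L) {
  if (inherits(images, "nt_image")) images <- list(images)
  if (!bits %in% c(8L, 16L)) stopf("bits must be 8 or 16")
  con <- file(path, open = "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L)
  # layout per page: [pixel data][IFD]; compute offsets up front
  n_entries <- 9L
  ifd_size <- 2 + n_entries * 12 + 4
  offset <- 8L
  layout <- list()
  for (img in images) {
    px <- img$pixels
    nbytes <- nrow(px) * ncol(px) * (bits / 8L)
    layout[[length(layout) + 1]] <- list(data_off = offset, ifd_off = offset + nbytes)
    offset <- offset + nbytes + ifd_size
  }
  w4(layout[[1]]$ifd_off)  # header pointer to the first IFD
  for (p in seq_along(images)) {
    img <- images[[p]]
    px <- img$pixels
    h <- nrow(px); w <- ncol(px)
    maxval <- 2^bits - 1
    vals <- as.integer(pmin(pmax(round(t(px)), 0), maxval))
    if (bits == 8L) {
      writeBin(as.raw(vals), con)
    } else {
      vals <- ifelse(vals > 32767L, vals - 65536L, vals)
      writeBin(vals, con, size = 2L, endian = "little")
    }
    entry <- function(tag, typ, cnt, val) { w2(tag); w2(typ); w4(cnt); w4(val) }
    w2(n_entries)
    entry(256L, 4L, 1L, w)                     # width
    entry(257L, 4L, 1L, h)                     # height
    entry(258L, 3L, 1L, bits)                  # bits per sample
    entry(259L, 3L, 1L, 1L)                    # no compression
    entry(262L, 3L, 1L, 1L)                    # BlackIsZero
    entry(273L, 4L, 1L, layout[[p]]$data_off)  # strip offset
    entry(277L, 3L, 1L, 1L)                    # samples per pixel
    entry(278L, 4L, 1L, h)                     # rows per strip
    entry(279L, 4L, 1L, h * w * (bits / 8L))   # strip byte count
    w4(if (p < length(images)) layout[[p + 1]]$ifd_off else 0L)
  }
  invisible(path)
}
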
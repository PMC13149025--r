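# Minimal baseline TIFF IO (uncompressed, single-sample grayscale).
#
# Enough for the two-channel STED fixtures: 8/16-bit unsigned or 32-bit
# float, little- or big-endian on read; 32-bit float little-endian on write.
# Multi-page files map to list elements (one page per channel).

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L)

#' Read a grayscale TIFF
#'
#' Minimal baseline-TIFF reader (uncompressed, one sample per pixel,
#' 8/16-bit unsigned or 32-bit float). Each page becomes a numeric matrix
#' (rows = image rows).
#'
#' @param path file path.
#' @return list of matrices, one per page.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
            else stop_mfx("not a TIFF file: %s", path)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", 1, 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", 1, 4,
                               endian = endian)
  if (u16(2) != 42L) stop_mfx("bad TIFF magic in %s", path)
  ifd_off <- u32(4)
  pages <- list()
  while (ifd_off != 0) {
    n_entries <- u16(ifd_off)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tag <- u16(e); type <- u16(e + 2); count <- u32(e + 4)
      size <- c(1, 1, 2, 4, 8)[type]  # BYTE ASCII SHORT LONG RATIONAL
      total <- size * count
      voff <- if (total <= 4) e + 8 else u32(e + 8)
      vals <- if (type == 3) {
        vapply(seq_len(count) - 1L, function(k) u16(voff + 2 * k), integer(1))
      } else if (type == 4) {
        vapply(seq_len(count) - 1L, function(k) u32(voff + 4 * k), integer(1))
      } else NULL
      tags[[as.character(tag)]] <- vals
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    width <- g(256); height <- g(257)
    bits <- g(258, 1L)[1]; comp <- g(259, 1L)
    fmt <- g(339, 1L)[1]
    spp <- g(277, 1L)
    if (comp != 1L) stop_mfx("compressed TIFF not supported")
    if (spp != 1L) stop_mfx("only single-sample (grayscale) TIFF supported")
    offs <- g(273); counts <- g(279)
    buf <- raw[unlist(lapply(seq_along(offs), function(i)
      (offs[i] + 1):(offs[i] + counts[i])))]
    n <- width * height
    px <- if (fmt == 3L && bits == 32L) {
      readBin(buf, "double", n, 4, endian = endian)
    } else if (fmt %in% c(1L, 4L) && bits == 8L) {
      as.numeric(readBin(buf, "integer", n, 1, signed = FALSE, endian = endian))
    } else if (fmt %in% c(1L, 4L) && bits == 16L) {
      as.numeric(readBin(buf, "integer", n, 2, signed = FALSE, endian = endian))
    } else stop_mfx("unsupported TIFF sample format (bits=%d, format=%d)",
                    bits, fmt)
    pages[[length(pages) + 1L]] <- matrix(px, nrow = height, ncol = width,
                                          byrow = TRUE)
    ifd_off <- u32(ifd_off + 2 + n_entries * 12)
  }
  pages
}

#' Write matrices as a (multi-page) 32-bit float TIFF
#'
#' @param images a matrix or list of matrices (rows = image rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1, all(vapply(images, is.matrix, logical(1))))
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, 2, endian = "little")
  writeChar("II", con, 2, eos = NULL); w16(42)

  n_entries <- 10L
  ifd_bytes <- 2 + n_entries * 12 + 4
  # layout: header(8) | for each page: pixel data then IFD
  offset <- 8
  pix_off <- integer(length(images)); ifd_off <- integer(length(images))
  for (i in seq_along(images)) {
    nb <- length(images[[i]]) * 4
    pix_off[i] <- offset
    ifd_off[i] <- offset + nb
    offset <- offset + nb + ifd_bytes
  }
  w32(ifd_off[1])
  for (i in seq_along(images)) {
    img <- images[[i]]
    writeBin(as.numeric(t(img)), con, 4, endian = "little")
    entry <- function(tag, type, count, value) {
      w16(tag); w16(type); w32(count); w32(value)
    }
    w16(n_entries)
    entry(256, 4, 1, ncol(img))
    entry(257, 4, 1, nrow(img))
    entry(258, 3, 1, 32)
    entry(259, 3, 1, 1)           # no compression
    entry(262, 3, 1, 1)           # black-is-zero
    entry(273, 4, 1, pix_off[i])
    entry(277, 3, 1, 1)
    entry(278, 4, 1, nrow(img))
    entry(279, 4, 1, length(img) * 4)
    entry(339, 3, 1, 3)           # IEEE float
    w32(if (i < length(images)) ifd_off[i + 1] else 0)
  }
  invisible(path)
}
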
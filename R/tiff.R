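## Minimal multi-page TIFF codec: 16-bit unsigned grayscale, uncompressed,
## little-endian, one strip per page. No R TIFF package is available in the
## target environment, so the subset of the format the package needs is
## implemented here. Layout per page: pixel data first, then the IFD.

.TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
                Compression = 259L, Photometric = 262L, StripOffsets = 273L,
                SamplesPerPixel = 277L, RowsPerStrip = 278L,
                StripByteCounts = 279L, PlanarConfig = 284L)

.w16 <- function(con, x) writeBin(as.integer(x), con, size = 2L,
                                  endian = "little")
.w32 <- function(con, x) writeBin(as.integer(x), con, size = 4L,
                                  endian = "little")

#' Write a multi-page 16-bit TIFF
#'
#' Pages are the first array index; each page is written as one
#' uncompressed strip of unsigned 16-bit grayscale, little-endian.
#'
#' @param path output file path.
#' @param pages 3-D integer array (page, row, col) or a single matrix
#'   (row, col); values must lie in 0..65535.
#' @return \code{path}, invisibly.
#' @export
writeTiffStack <- function(path, pages) {
  if (is.matrix(pages)) pages <- array(pages, c(1L, dim(pages)))
  d <- dim(pages)
  if (length(d) != 3L) stop("'pages' must be a (page, row, col) array")
  if (min(pages) < 0 || max(pages) > 65535)
    stop("pixel values must lie in the 16-bit range 0..65535")
  np <- d[1]; nr <- d[2]; nc <- d[3]
  pageBytes <- 2L * nr * nc
  ifdBytes <- 2L + 12L * length(.TIFF_TAGS) + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  .w16(con, 42L)
  .w32(con, 8L + pageBytes)            # first IFD sits after first page data
  for (p in seq_len(np)) {
    dataOff <- 8L + (p - 1L) * (pageBytes + ifdBytes)
    ifdOff <- dataOff + pageBytes
    nextIfd <- if (p < np) ifdOff + ifdBytes + pageBytes else 0L
    ## row-major pixel data; writeBin size=2 truncates to the low 16 bits,
    ## which encodes unsigned values correctly
    .w16(con, as.vector(t(pages[p, , ])))
    .w16(con, length(.TIFF_TAGS))
    entry <- function(tag, type, value) {
      .w16(con, tag); .w16(con, type); .w32(con, 1L)
      if (type == 3L) { .w16(con, value); .w16(con, 0L) } else .w32(con, value)
    }
    entry(256L, 4L, nc)                # ImageWidth
    entry(257L, 4L, nr)                # ImageLength
    entry(258L, 3L, 16L)               # BitsPerSample
    entry(259L, 3L, 1L)                # Compression: none
    entry(262L, 3L, 1L)                # Photometric: BlackIsZero
    entry(273L, 4L, dataOff)           # StripOffsets
    entry(277L, 3L, 1L)                # SamplesPerPixel
    entry(278L, 4L, nr)                # RowsPerStrip
    entry(279L, 4L, pageBytes)         # StripByteCounts
    entry(284L, 3L, 1L)                # PlanarConfig: chunky
    .w32(con, nextIfd)
  }
  invisible(path)
}

#' Read a multi-page 16-bit TIFF
#'
#' Reads the uncompressed 16-bit grayscale subset written by
#' \code{\link{writeTiffStack}} (tolerating extra tags and multiple strips).
#'
#' @param path TIFF file path.
#' @return Integer array (page, row, col).
#' @export
readTiffStack <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L)
    stop("not a little-endian TIFF file: ", path)
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    nEntries <- u16(ifd)
    tags <- list()
    for (i in seq_len(nEntries)) {
      e <- ifd + 2 + (i - 1) * 12
      tag <- u16(e); type <- u16(e + 2); count <- u32(e + 4)
      size <- c(1, 1, 2, 4, 8)[type]
      valOff <- if (size * count <= 4) e + 8 else u32(e + 8)
      vals <- vapply(seq_len(count) - 1L, function(j) {
        if (type == 3L) u16(valOff + 2 * j) else u32(valOff + 4 * j)
      }, numeric(1))
      tags[[as.character(tag)]] <- vals
    }
    need <- function(tag) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) stop("TIFF tag ", tag, " missing in ", path)
      v
    }
    nc <- need(256L); nr <- need(257L)
    if (need(258L)[1] != 16L) stop("only 16-bit TIFF pages are supported")
    if (need(259L)[1] != 1L) stop("only uncompressed TIFF pages are supported")
    offs <- need(273L); counts <- need(279L)
    px <- integer(0)
    for (s in seq_along(offs)) {
      n <- counts[s] / 2
      px <- c(px, readBin(raw[(offs[s] + 1):(offs[s] + counts[s])],
                          "integer", n = n, size = 2L, signed = FALSE,
                          endian = "little"))
    }
    pages[[length(pages) + 1L]] <- matrix(px, nr, nc, byrow = TRUE)
    ifd <- u32(ifd + 2 + nEntries * 12)
  }
  out <- array(0L, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (p in seq_along(pages)) out[p, , ] <- pages[[p]]
  out
}
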
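# Minimal baseline TIFF I/O: single-channel, 16-bit unsigned, uncompressed,
# little-endian.  No TIFF package ships with the pre-installed R stack, and
# the format subset needed here (one grayscale strip) is small enough to
# write directly.  Readers of vendor TIFFs beyond this subset get a clear
# error rather than silent misparsing.

#' Write a matrix as a 16-bit grayscale TIFF
#'
#' Values are clamped to `[0, 65535]` and rounded. Rows of the matrix map
#' to image rows (y), columns to x.
#'
#' @param img numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff16 <- function(img, path) {
  stopifnot(is.matrix(img))
  h <- nrow(img); w <- ncol(img)
  vals <- as.integer(pmin(pmax(round(t(img)), 0), 65535)) # row-major
  nbytes <- 2L * w * h
  con <- file(path, "wb")
  on.exit(close(con))
  wle <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  writeBin(charToRaw("II"), con)
  wle(42L, 2L)
  wle(8L + nbytes, 4L) # IFD offset: header + pixel data
  # pixel data at offset 8
  writeBin(ifelse(vals > 32767L, vals - 65536L, vals), con, size = 2L, endian = "little")
  entry <- function(tag, type, count, value) {
    wle(tag, 2L); wle(type, 2L); wle(count, 4L)
    if (type == 3L) { # SHORT: value left-justified in 4 bytes
      wle(value, 2L); wle(0L, 2L)
    } else {
      wle(value, 4L)
    }
  }
  wle(9L, 2L) # entry count
  entry(256L, 4L, 1L, w)        # ImageWidth
  entry(257L, 4L, 1L, h)        # ImageLength
  entry(258L, 3L, 1L, 16L)      # BitsPerSample
  entry(259L, 3L, 1L, 1L)       # Compression: none
  entry(262L, 3L, 1L, 1L)       # Photometric: BlackIsZero
  entry(273L, 4L, 1L, 8L)       # StripOffsets
  entry(277L, 3L, 1L, 1L)       # SamplesPerPixel
  entry(278L, 4L, 1L, h)        # RowsPerStrip
  entry(279L, 4L, 1L, nbytes)   # StripByteCounts
  wle(0L, 4L) # no further IFD
  invisible(path)
}

#' Read a 16-bit grayscale TIFF written by [write_tiff16()]
#'
#' Supports uncompressed single-sample little- or big-endian images with
#' one or more strips; anything else raises an error.
#'
#' @param path file path.
#' @return numeric matrix (rows = image rows).
#' @export
read_tiff16 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  rint <- function(off, size, n = 1L) {
    readBin(raw[(off + 1):(off + size * n)], "integer",
            n = n, size = size, signed = size == 4L, endian = endian)
  }
  stopifnot(rint(2, 2) == 42L)
  ifd <- rint(4, 4)
  n_entries <- rint(ifd, 2)
  tags <- list()
  type_size <- c(`1` = 1L, `3` = 2L, `4` = 4L)
  for (i in seq_len(n_entries)) {
    e <- ifd + 2 + (i - 1) * 12
    tag <- rint(e, 2); type <- rint(e + 2, 2); count <- rint(e + 4, 4)
    sz <- type_size[as.character(type)]
    if (is.na(sz)) next # skip rationals etc.
    total <- sz * count
    voff <- if (total <= 4) e + 8 else rint(e + 8, 4)
    tags[[as.character(tag)]] <- rint(voff, sz, count)
  }
  need <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
  w <- need(256); h <- need(257)
  if (is.null(w) || is.null(h)) stop("TIFF lacks dimensions")
  if ((need(258, 16L))[1] != 16L) stop("only 16-bit TIFFs are supported")
  if (need(259, 1L) != 1L) stop("only uncompressed TIFFs are supported")
  if (need(277, 1L) != 1L) stop("only single-sample TIFFs are supported")
  offs <- need(273); counts <- need(279)
  vals <- integer(0)
  for (i in seq_along(offs)) {
    n <- counts[i] %/% 2L
    v <- readBin(raw[(offs[i] + 1):(offs[i] + counts[i])], "integer",
                 n = n, size = 2L, signed = FALSE, endian = endian)
    vals <- c(vals, v)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}
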
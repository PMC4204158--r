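#' Rasters and raster I/O
#'
#' A raster is a plain numeric matrix indexed `[row, col]` with the origin at
#' the top-left corner and unit pixel spacing.  Intensities from integer
#' image files are scaled to `[0, 1]`; float TIFF data pass through
#' unchanged.  Binary masks use 0 = background, nonzero = foreground,
#' written to disk as 0/255 PNG.
#'
#' @name raster
NULL

assert_raster <- function(x, min_dim = 3L, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  if (nrow(x) < min_dim || ncol(x) < min_dim)
    stop(sprintf("'%s' must be at least %dx%d (got %dx%d)",
                 name, min_dim, min_dim, nrow(x), ncol(x)), call. = FALSE)
  invisible(x)
}

assert_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must share one grid: %s vs %s", what,
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(NULL)
}

#' Read a grayscale raster from PNG or TIFF
#'
#' Integer images (8/16-bit) are scaled to `[0, 1]`; float TIFF values pass
#' through.  RGB(A) input is converted to luminance
#' (0.2126 R + 0.7152 G + 0.0722 B).
#'
#' @param path Path to a single-frame PNG or TIFF file.
#' @return A numeric matrix (rows = image rows, top-left origin).
#' @export
read_raster <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      frames <- tiff::readTIFF(path, all = TRUE)
      if (length(frames) != 1L)
        stop("multi-frame TIFF not supported: ", path, call. = FALSE)
      frames[[1L]]
    },
    stop("unsupported image format '", ext, "': ", path, call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    img <- if (nc >= 3L)
      0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
    else img[, , 1L]
  }
  assert_raster(img, min_dim = 1L, name = path)
  img
}

#' Write a binary mask as a 0/255 grayscale PNG
#'
#' @param mask Numeric or logical matrix; nonzero/`TRUE` marks foreground.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- (mask != 0) * 1.0
  png::writePNG(m, path)
  invisible(path)
}

#' Write a raster as a 32-bit float TIFF
#'
#' Used for signed distance functions and interaction fields, whose values
#' fall outside `[0, 1]`; the file is a plain uncompressed IEEE-float
#' single-strip TIFF, readable by any libtiff-based tool (and by
#' [read_raster()]).  Written directly because the graphics TIFF writers
#' only define storage for values in `[0, 1]`.
#'
#' @param x Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster_tiff <- function(x, path) {
  assert_raster(x, min_dim = 1L)
  h <- nrow(x); w <- ncol(x)
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  u32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  tag <- function(id, type, count, value) { u16(id); u16(type); u32(count); u32(value) }
  writeChar("II", con, eos = NULL); u16(42L); u32(8L)     # header, IFD at 8
  ntag <- 10L
  data_off <- 8L + 2L + ntag * 12L + 4L
  u16(ntag)
  tag(256L, 4L, 1L, w)                 # ImageWidth
  tag(257L, 4L, 1L, h)                 # ImageLength
  tag(258L, 3L, 1L, 32L)               # BitsPerSample
  tag(259L, 3L, 1L, 1L)                # Compression: none
  tag(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
  tag(273L, 4L, 1L, data_off)          # StripOffsets
  tag(277L, 3L, 1L, 1L)                # SamplesPerPixel
  tag(278L, 4L, 1L, h)                 # RowsPerStrip
  tag(279L, 4L, 1L, 4L * h * w)        # StripByteCounts
  tag(339L, 3L, 1L, 3L)                # SampleFormat: IEEE float
  u32(0L)                              # no next IFD
  writeBin(as.vector(t(x)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a binary mask image
#'
#' Reads a raster and binarizes at 0.5 (masks are stored as 0/255 PNG).
#'
#' @param path Path to a mask image.
#' @return Integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  m <- read_raster(path)
  (m >= 0.5) * 1L
}
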
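#' Read a grayscale image
#'
#' Reads PNG, TIFF or PGM rasters into a [GrayImage-class]. RGB input is
#' collapsed to luminance with the Rec. 601 weighting
#' (0.299 R + 0.587 G + 0.114 B); integer bit depths are rescaled to
#' \eqn{[0,1]}; floating-point input is clipped to \eqn{[0,1]}.
#'
#' @param path path to a PNG, TIFF or PGM (P2/P5) file.
#' @return A [GrayImage-class] with pixels indexed \code{[row, col]}.
#' @seealso [saveGray()]
#' @export
loadGray <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    m <- readPGM(path)
  } else {
    dat <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(dat)) == 3L) {
      if (dim(dat)[3] < 3L) dat <- dat[, , 1L]
      else dat <- 0.299 * dat[, , 1] + 0.587 * dat[, , 2] + 0.114 * dat[, , 3]
    }
    ## EBImage stores rasters [x, y]; transpose to [row, col]
    m <- t(dat)
  }
  if (length(dim(m)) != 2L || any(dim(m) == 0L))
    stop("not a 2-D raster: ", path)
  grayImage(clip01(m))
}

#' Write a grayscale image
#'
#' Writes 8-bit PNG/TIFF via EBImage, or ASCII PGM (P2). Quantization to
#' 8 bits bounds the round-trip error by half a gray step (1/255 in the worst
#' case after rounding).
#'
#' @param img a [GrayImage-class] (or numeric matrix in \eqn{[0,1]}).
#' @param path output path; format chosen from the extension
#'   (png/tif/tiff/pgm).
#' @return \code{path}, invisibly.
#' @export
saveGray <- function(img, path) {
  p <- pixels(grayImage(img))
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") {
    writePGM(p, path)
  } else if (ext %in% c("png", "tif", "tiff")) {
    EBImage::writeImage(EBImage::Image(t(p)), path, type = ext)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

## Plain-text/binary PGM support (P2 and P5); maxval up to 65535.
readPGM <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  nextToken <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") stop("truncated PGM header")
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch %in% c("\n", "")) break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) { if (nzchar(tok)) break else next }
      tok <- paste0(tok, ch)
    }
    tok
  }
  w <- as.integer(nextToken()); h <- as.integer(nextToken())
  maxv <- as.integer(nextToken())
  if (any(is.na(c(w, h, maxv))) || w < 1L || h < 1L || maxv < 1L)
    stop("malformed PGM header in ", path)
  n <- w * h
  if (magic == "P5") {
    bytes <- if (maxv > 255L) 2L else 1L
    raw <- readBin(con, "integer", n = n, size = bytes, signed = FALSE,
                   endian = "big")
    if (length(raw) < n) stop("truncated PGM pixel data in ", path)
    vals <- raw
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])
    if (length(vals) < n) stop("truncated PGM pixel data in ", path)
    vals <- vals[seq_len(n)]
  }
  matrix(vals / maxv, nrow = h, ncol = w, byrow = TRUE)
}

writePGM <- function(p, path) {
  v <- round(p * 255)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("P2", paste(ncol(p), nrow(p)), "255"), con)
  write(t(v), file = con, ncolumns = ncol(p))
  invisible(path)
}

#' Crop a square region of interest
#'
#' Extracts a \code{size x size} sub-raster with no resampling, e.g. the
#' 128 x 128 region of interest cut from a 640 x 480 scan. Coordinates are
#' 0-based \code{(row, col)} of the top-left corner.
#'
#' @param img a [GrayImage-class].
#' @param top,left 0-based corner of the crop window.
#' @param size crop side length in pixels.
#' @return A [GrayImage-class] of dimension \code{size x size}.
#' @examples
#' img <- grayImage(matrix(runif(480 * 640), 480, 640))
#' roi <- cropImage(img, 100, 200, 128)
#' dim(roi)
#' @export
cropImage <- function(img, top, left, size) {
  p <- pixels(img)
  if (top < 0 || left < 0 || top + size > nrow(p) || left + size > ncol(p))
    stop(sprintf("crop window (%d,%d)+%d lies outside the %d x %d image",
                 top, left, size, nrow(p), ncol(p)))
  grayImage(p[(top + 1):(top + size), (left + 1):(left + size), drop = FALSE])
}

#' 256-bin gray-level histogram
#'
#' Bins intensity p into 8-bit level \code{floor(p * 255 + 0.5)}. The counts
#' always sum to the pixel count, and for typical B-mode material the mass is
#' concentrated in a narrow band of levels -- the low dynamic range the
#' enhancement stages exist to correct.
#'
#' @param img a [GrayImage-class].
#' @return Integer vector of 256 counts named by gray level "0".."255".
#' @export
grayHistogram <- function(img) {
  p <- pixels(img)
  counts <- tabulate(floor(p * 255 + 0.5) + 1L, nbins = 256L)
  names(counts) <- 0:255
  counts
}
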
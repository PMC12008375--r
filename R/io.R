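# Image file handling.  Everything internal works on base R matrices/arrays
# in [0,1] with dim (H, W) or (H, W, 3); readers normalise to that layout.

#' Read an image file
#'
#' Supports PNG, TIFF, JPEG (through EBImage) and the portable anymap
#' formats PGM/PPM (P2/P3/P5/P6).  Values are returned in [0,1] as an
#' H x W matrix (grayscale) or H x W x 3 array (RGB); an alpha channel is
#' dropped.
#'
#' @param path file path.
#' @return numeric matrix or array in [0,1].
#' @export
readImageFile <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    ppm = , pgm = , pnm = readPNM(path),
    jpg = , jpeg = {
      img <- EBImage::readImage(path)
      d <- EBImage::imageData(img)
      # EBImage stores (x, y[, c]): transpose back to (row, col)
      if (length(dim(d)) == 2L) t(d) else aperm(d, c(2L, 1L, 3L))
    },
    stop("unsupported image format: ", ext))
  if (length(dim(x)) == 3L && dim(x)[3] > 3L) x <- x[, , 1:3]
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) x <- x[, , 1L]
  x
}

# Plain PNM reader (ASCII P2/P3 and binary P5/P6, maxval <= 255).
readPNM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P3", "P5", "P6")) stop("not a supported PNM file")
  vals <- integer(0)
  header <- integer(0)
  # read header tokens (width, height, maxval), skipping comments
  readToken <- function() {
    tok <- ""
    repeat {
      ch <- rawToChar(readBin(con, "raw", 1L))
      if (length(ch) == 0 || ch == "") stop("truncated PNM header")
      if (ch == "#") { repeat { c2 <- rawToChar(readBin(con, "raw", 1L)); if (c2 == "\n") break } ; next }
      if (grepl("[[:space:]]", ch)) { if (nzchar(tok)) return(tok) else next }
      tok <- paste0(tok, ch)
    }
  }
  w <- as.integer(readToken()); h <- as.integer(readToken())
  maxval <- as.integer(readToken())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  if (magic %in% c("P5", "P6")) {
    vals <- as.integer(readBin(con, "raw", n))
  } else {
    txt <- paste(readLines(con, warn = FALSE), collapse = " ")
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])[seq_len(n)]
  }
  if (nch == 1L) {
    matrix(vals / maxval, h, w, byrow = TRUE)
  } else {
    a <- array(0, c(h, w, 3L))
    m <- matrix(vals, ncol = 3L, byrow = TRUE) / maxval
    for (k in 1:3) a[, , k] <- matrix(m[, k], h, w, byrow = TRUE)
    a
  }
}

#' Write a grayscale image or mask as 8-bit PNG
#'
#' @param x H x W matrix; values clamped to [0,1].  Masks should be 0/1 and
#'   are written with values \{0, 255\}.
#' @param path output path.
#' @export
writeGrayPNG <- function(x, path) {
  png::writePNG(pmin(pmax(x, 0), 1), path)
  invisible(path)
}
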
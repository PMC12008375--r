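# Preprocessing pipeline: grayscale conversion -> intensity normalisation ->
# contrast-limited adaptive histogram equalisation (CLAHE).  The CLAHE step
# counteracts the uneven illumination typical of fundus photographs and is
# what makes faint thin vessels separable from background.

#' Create a preprocessing configuration
#'
#' @param claheClipLimit CLAHE clip limit on 8-bit-equivalent tile
#'   histograms; community default 2.0 for fundus work.
#' @param claheTileGrid tile grid (rows, cols); default 8 x 8.
#' @param normalizationMode \code{"zscore_rescale"} (standardise then rescale
#'   to [0,1]) or \code{"minmax"}.
#' @return A \linkS4class{PreprocessConfig}.
#' @export
preprocessConfig <- function(claheClipLimit = 2.0, claheTileGrid = c(8L, 8L),
                             normalizationMode = "zscore_rescale") {
  new("PreprocessConfig", claheClipLimit = claheClipLimit,
      claheTileGrid = as.integer(claheTileGrid),
      normalizationMode = normalizationMode)
}

#' Convert an RGB image to grayscale
#'
#' Luminance-weighted combination with ITU-R BT.601 weights
#' (0.299, 0.587, 0.114).
#'
#' @param rgb H x W x 3 array with values in [0,1].
#' @return H x W matrix in [0,1].
#' @export
toGrayscale <- function(rgb) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3] != 3L)
    stop("toGrayscale expects an H x W x 3 array")
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' Normalise image intensities to [0,1]
#'
#' \code{"zscore_rescale"} subtracts the mean, divides by the standard
#' deviation and then affinely rescales the result to [0,1], making the
#' output invariant to affine intensity transforms of the input.
#' \code{"minmax"} rescales directly.  A constant image is returned as
#' all-0.5 (degenerate-input convention).
#'
#' @param gray H x W matrix.
#' @param mode \code{"zscore_rescale"} or \code{"minmax"}.
#' @return H x W matrix with range [0,1] (or all 0.5).
#' @export
normalizeImage <- function(gray, mode = c("zscore_rescale", "minmax")) {
  mode <- match.arg(mode)
  rng <- range(gray)
  if (diff(rng) == 0) return(matrix(0.5, nrow(gray), ncol(gray)))
  if (mode == "zscore_rescale") {
    z <- (gray - mean(gray)) / stats::sd(gray)
    rng <- range(z)
    (z - rng[1]) / diff(rng)
  } else {
    (gray - rng[1]) / diff(rng)
  }
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Per-tile histogram equalisation with clipped histograms and bilinear
#' interpolation between neighbouring tile mappings (delegated to
#' \code{EBImage::clahe}).  Geometry is preserved and the output lies in
#' [0,1].  A zero-dynamic-range (constant) image is returned unchanged.
#'
#' @param gray H x W matrix in [0,1].
#' @param config a \linkS4class{PreprocessConfig}.
#' @return H x W matrix in [0,1].
#' @export
claheEnhance <- function(gray, config = preprocessConfig()) {
  stopifnot(is(config, "PreprocessConfig"))
  grid <- config@claheTileGrid
  if (any(grid > dim(gray)))
    stop("CLAHE tile grid larger than the image")
  if (diff(range(gray)) == 0) return(gray)
  # EBImage images are (x, y); our first dim is rows, so nx counts tile rows
  out <- EBImage::imageData(EBImage::clahe(EBImage::Image(gray),
                                           nx = grid[1], ny = grid[2],
                                           limit = config@claheClipLimit))
  out <- pmin(pmax(out, 0), 1)
  dim(out) <- dim(gray)
  out
}

#' Full preprocessing pipeline
#'
#' Grayscale conversion (skipped for single-channel input), normalisation,
#' then CLAHE, in that order.  Deterministic and side-effect free.
#'
#' @param img H x W matrix or H x W x 3 array in [0,1].
#' @param config a \linkS4class{PreprocessConfig}.
#' @return preprocessed H x W matrix in [0,1].
#' @export
preprocessImage <- function(img, config = preprocessConfig()) {
  g <- if (length(dim(img)) == 3L) toGrayscale(img) else img
  g <- normalizeImage(g, config@normalizationMode)
  claheEnhance(g, config)
}
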
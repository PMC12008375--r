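# Sliding-window patch extraction, paired random patch sampling,
# augmentation and overlap-averaged stitching.

newPatchGrid <- function(patches, coords, canvasSize, patchSize) {
  new("PatchGrid", patches = patches,
      coords = matrix(as.integer(coords), ncol = 2),
      canvasSize = as.integer(canvasSize), patchSize = as.integer(patchSize))
}

#' @describeIn extractGrid number of patches in a grid.
#' @export
setMethod("length", "PatchGrid", function(x) length(x@patches))

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf("PatchGrid: %d patches of %dx%d over a %dx%d canvas\n",
              length(object@patches), object@patchSize[1], object@patchSize[2],
              object@canvasSize[1], object@canvasSize[2]))
})

#' Accessors for PatchGrid
#'
#' @param x a \linkS4class{PatchGrid}.
#' @return \code{patches()}: list of patch arrays; \code{patchCoords()}:
#'   integer matrix of 0-based (row, col) top-left positions;
#'   \code{canvasSize()}: integer(2).
#' @export
patches <- function(x) x@patches

#' @rdname patches
#' @export
patchCoords <- function(x) x@coords

#' @rdname patches
#' @export
canvasSize <- function(x) x@canvasSize

# 0-based sliding-window start positions along one axis with edge snapping:
# the last window is clamped so the canvas edge is always covered.
slidePositions <- function(n, k, stride) {
  pos <- seq.int(0L, max(n - k, 0L), by = stride)
  if (pos[length(pos)] != n - k) pos <- c(pos, n - k)
  as.integer(pos)
}

#' Extract a deterministic sliding-window patch grid
#'
#' Raster-order (row-major) placement; the last row/column positions are
#' edge-snapped so every canvas pixel is covered for any stride.
#'
#' @param image H x W matrix or H x W x C array.
#' @param patchSize patch height/width (scalar or length 2).
#' @param stride step between window origins (scalar or length 2), >= 1.
#' @return A \linkS4class{PatchGrid}.
#' @export
extractGrid <- function(image, patchSize = 64L, stride = 32L) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  ps <- as.integer(rep(patchSize, length.out = 2))
  st <- as.integer(rep(stride, length.out = 2))
  if (any(ps > c(H, W))) stop("patch larger than image")
  if (any(st < 1L)) stop("stride must be >= 1")
  rows <- slidePositions(H, ps[1], st[1])
  cols <- slidePositions(W, ps[2], st[2])
  coords <- cbind(rep(rows, each = length(cols)), rep(cols, times = length(rows)))
  tiles <- lapply(seq_len(nrow(coords)), function(i) {
    r <- coords[i, 1]; c <- coords[i, 2]
    if (length(d) == 2L) image[r + seq_len(ps[1]), c + seq_len(ps[2])]
    else image[r + seq_len(ps[1]), c + seq_len(ps[2]), , drop = FALSE]
  })
  newPatchGrid(tiles, coords, c(H, W), ps)
}

#' Sample random training patches whose centres lie inside the FOV
#'
#' Top-left positions are drawn uniformly; a draw is kept only if the patch
#' centre falls inside the field of view, so every training tile contains
#' retina.  Image and mask are cropped identically.  Reproducible under
#' \code{seed}; the caller's RNG state is untouched.
#'
#' @param image,mask,fov H x W matrices sharing geometry.
#' @param patchSize patch height/width.
#' @param nPatches number of patches (>= 1).
#' @param seed integer seed.
#' @return list with \code{image} and \code{mask} \linkS4class{PatchGrid}s
#'   sharing coordinates.
#' @export
samplePatches <- function(image, mask, fov, patchSize = 64L, nPatches = 100L,
                          seed = 1L) {
  if (nPatches < 1) stop("nPatches must be >= 1")
  d <- dim(image)
  ps <- as.integer(rep(patchSize, length.out = 2))
  if (any(ps > d)) stop("patch larger than image")
  maxR <- d[1] - ps[1]; maxC <- d[2] - ps[2]
  withSeed(seed, {
    coords <- matrix(0L, nPatches, 2)
    got <- 0L
    tries <- 0L
    while (got < nPatches) {
      tries <- tries + 1L
      if (tries > 1000L * nPatches)
        stop("FOV too small to place any patch")
      r <- sample.int(maxR + 1L, 1L) - 1L
      c <- sample.int(maxC + 1L, 1L) - 1L
      if (fov[r + ps[1] %/% 2L + 1L, c + ps[2] %/% 2L + 1L] >= 0.5) {
        got <- got + 1L
        coords[got, ] <- c(r, c)
      }
    }
    imgTiles <- lapply(seq_len(nPatches), function(i)
      image[coords[i, 1] + seq_len(ps[1]), coords[i, 2] + seq_len(ps[2])])
    mskTiles <- lapply(seq_len(nPatches), function(i)
      mask[coords[i, 1] + seq_len(ps[1]), coords[i, 2] + seq_len(ps[2])])
    list(image = newPatchGrid(imgTiles, coords, d, ps),
         mask = newPatchGrid(mskTiles, coords, d, ps))
  })
}

# counter-clockwise quarter rotation: out[i, j] = m[j, W + 1 - i]
rot90ccw <- function(m) {
  tm <- t(m)
  tm[rev(seq_len(nrow(tm))), , drop = FALSE]
}

#' Jointly augment an image/mask tile pair
#'
#' Applies one random spatial transform -- counter-clockwise quarter
#' rotations, horizontal/vertical flips and mild isotropic scale jitter --
#' identically to both tiles.  The mask is re-binarised (nearest-neighbour
#' under scaling) and output geometry always equals input geometry (scale
#' jitter is cropped or reflected-padded back).
#'
#' @param imageTile,maskTile square matrices of equal size.
#' @param seed integer seed (the caller's RNG state is untouched).
#' @param rot90s,flips logical; enable quarter rotations / flips.
#' @param scaleJitter numeric(2) scale-factor range, or NULL to disable.
#' @return list \code{(image, mask)} of transformed tiles.
#' @export
augmentPair <- function(imageTile, maskTile, seed = 1L, rot90s = TRUE,
                        flips = TRUE, scaleJitter = NULL) {
  stopifnot(all(dim(imageTile) == dim(maskTile)))
  withSeed(seed, {
    img <- imageTile; msk <- maskTile
    if (isTRUE(rot90s)) {
      k <- sample.int(4L, 1L) - 1L
      if (k > 0) for (i in seq_len(k)) { img <- rot90ccw(img); msk <- rot90ccw(msk) }
    }
    if (isTRUE(flips)) {
      if (stats::runif(1) < 0.5) { img <- img[, rev(seq_len(ncol(img)))]; msk <- msk[, rev(seq_len(ncol(msk)))] }
      if (stats::runif(1) < 0.5) { img <- img[rev(seq_len(nrow(img))), ]; msk <- msk[rev(seq_len(nrow(msk))), ] }
    }
    if (!is.null(scaleJitter)) {
      s <- stats::runif(1, scaleJitter[1], scaleJitter[2])
      if (abs(s - 1) > 1e-8) {
        h <- nrow(img); w <- ncol(img)
        nh <- max(1L, round(h * s)); nw <- max(1L, round(w * s))
        img2 <- EBImage::imageData(EBImage::resize(EBImage::Image(img), nh, nw))
        msk2 <- EBImage::imageData(EBImage::resize(EBImage::Image(msk), nh, nw,
                                                   filter = "none"))
        img <- centerFit(img2, h, w)
        msk <- (centerFit(msk2, h, w) > 0.5) * 1
      }
    }
    list(image = img, mask = msk)
  })
}

# crop (if larger) or reflect-pad (if smaller) back to h x w, centred
centerFit <- function(m, h, w) {
  nh <- nrow(m); nw <- ncol(m)
  if (nh >= h) {
    r0 <- (nh - h) %/% 2L
    m <- m[r0 + seq_len(h), , drop = FALSE]
  } else {
    pad <- h - nh
    top <- pad %/% 2L; bot <- pad - top
    m <- rbind(m[rev(seq_len(top)), , drop = FALSE], m,
               m[nh + 1L - seq_len(bot), , drop = FALSE])
  }
  nw <- ncol(m)
  if (nw >= w) {
    c0 <- (nw - w) %/% 2L
    m <- m[, c0 + seq_len(w), drop = FALSE]
  } else {
    pad <- w - nw
    left <- pad %/% 2L; right <- pad - left
    m <- cbind(m[, rev(seq_len(left)), drop = FALSE], m,
               m[, nw + 1L - seq_len(right), drop = FALSE])
  }
  m
}

#' Stitch overlapping patch predictions back onto the canvas
#'
#' Per-pixel mean of all patches covering the pixel; the divisor is the
#' per-pixel coverage count.  Errors if any canvas pixel is uncovered
#' (impossible for grids from [extractGrid()]).
#'
#' @param grid a \linkS4class{PatchGrid} of matrices or H x W x C arrays.
#' @return matrix (or H x W x C array) of averaged values.
#' @export
stitchGrid <- function(grid) {
  stopifnot(is(grid, "PatchGrid"))
  H <- grid@canvasSize[1]; W <- grid@canvasSize[2]
  ps <- grid@patchSize
  first <- grid@patches[[1]]
  nc <- if (length(dim(first)) >= 3L) dim(first)[3] else 1L
  acc <- array(0, c(H, W, nc))
  cnt <- matrix(0, H, W)
  for (i in seq_along(grid@patches)) {
    r <- grid@coords[i, 1]; c <- grid@coords[i, 2]
    ri <- r + seq_len(ps[1]); ci <- c + seq_len(ps[2])
    p <- grid@patches[[i]]
    if (length(dim(p)) < 3L) dim(p) <- c(dim(p), 1L)
    acc[ri, ci, ] <- acc[ri, ci, , drop = FALSE] + p[, , , drop = FALSE]
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  if (any(cnt == 0)) stop("uncovered pixel: grid does not cover the canvas")
  for (k in seq_len(nc)) acc[, , k] <- acc[, , k] / cnt
  if (nc == 1L) acc[, , 1L] else acc
}
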
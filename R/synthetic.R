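# Synthetic fundus-like image generator.  Vessels are rendered as connected
# curvilinear trees: each tree grows by a biased random walk with bounded
# curvature, branches dichotomously with a small per-step probability, and
# its width shrinks by a fixed factor per branching level, producing the
# multi-scale geometry (wide trunks down to faint <=2 px tips) that makes
# real vessel segmentation hard.  The background carries a smooth
# illumination gradient, Gaussian noise and lesion-like blobs that are
# deliberately absent from the ground truth.

#' Create a synthetic-generator configuration
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: a 256x256 canvas with 4 vessel trees whose stem widths span 1-6 px,
#' moderate contrast, a 25\% peak-to-peak illumination drift, lesion blobs and
#' mild sensor noise.
#'
#' @param canvasSize integer(2) image height/width in pixels (>= 64).
#' @param nTrees number of vessel root stems.
#' @param branchDecay width shrink factor per branching level, in (0,1).
#' @param minWidth,maxWidth stem width range in pixels.
#' @param contrastRange vessel-vs-background intensity gap range in [0,1].
#' @param nLesions number of bright/dark elliptical lesion blobs.
#' @param illuminationGradient peak-to-peak background drift in [0,1].
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param seed integer RNG seed.
#' @return A \linkS4class{SynthConfig}.
#' @examples
#' cfg <- synthConfig(seed = 7)
#' s <- generateSample(cfg)
#' mean(s$mask[s$fov == 1])  # vessel-pixel fraction of the field of view
#' @export
synthConfig <- function(canvasSize = c(256L, 256L), nTrees = 4L,
                        branchDecay = 0.72, minWidth = 1, maxWidth = 6,
                        contrastRange = c(0.25, 0.55), nLesions = 3L,
                        illuminationGradient = 0.25, noiseSd = 0.03,
                        seed = 1L) {
  new("SynthConfig", canvasSize = as.integer(canvasSize),
      nTrees = as.integer(nTrees), branchDecay = branchDecay,
      minWidth = minWidth, maxWidth = maxWidth,
      contrastRange = as.numeric(contrastRange), nLesions = as.integer(nLesions),
      illuminationGradient = illuminationGradient, noiseSd = noiseSd,
      seed = as.integer(seed))
}

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf("SynthConfig: %dx%d canvas, %d trees (width %.1f-%.1f px, decay %.2f), %d lesions, seed %d\n",
              object@canvasSize[1], object@canvasSize[2], object@nTrees,
              object@minWidth, object@maxWidth, object@branchDecay,
              object@nLesions, object@seed))
})

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Grow one vessel tree into `mask` (binary) and `profile` (contrast
# amplitude, max-combined); both are mutated in place through the compiled
# stamping kernels.  Branches are a work queue of walk states; a child
# inherits its parent's cumulative step count so tree size stays bounded.
growTree <- function(mask, profile, cx, cy, rfov, cfg) {
  H <- nrow(mask); W <- ncol(mask)
  gap <- stats::runif(1, cfg@contrastRange[1], cfg@contrastRange[2])
  ang0 <- stats::runif(1, 0, 2 * pi)
  r0 <- 0.88 * rfov
  start <- c(cy + r0 * sin(ang0), cx + r0 * cos(ang0))
  heading <- ang0 + pi + stats::runif(1, -0.5, 0.5)  # roughly inward
  w0 <- stats::runif(1, max(cfg@minWidth, 0.6 * cfg@maxWidth), cfg@maxWidth)
  queue <- list(list(pos = start, dir = heading, w = w0))
  # per-tree centreline budget keeps tree mass bounded despite dichotomous
  # branching (scaled to the canvas so larger canvases grow larger trees)
  budget <- 3.5 * max(H, W)
  total <- 0
  stepLen <- 0.7
  wmin <- 0.8
  while (length(queue) > 0 && total < budget) {
    br <- queue[[1]]
    queue <- queue[-1]
    pos <- br$pos; dir <- br$dir; w <- br$w
    drift <- 0
    while (w >= wmin && total < budget &&
           sqrt((pos[1] - cy)^2 + (pos[2] - cx)^2) <= 0.97 * rfov) {
      r <- max(w / 2, 0.9)  # stamp radius floor keeps the rasterised path connected
      stamp_disk_cpp(mask, pos[1], pos[2], r)
      # thin branches render with lower contrast (faint vessel tips)
      amp <- gap * (0.35 + 0.65 * min(1, w / (0.6 * cfg@maxWidth)))
      stamp_amp_cpp(profile, pos[1], pos[2], r + 0.5, amp)
      # bounded-curvature biased random walk
      drift <- 0.9 * drift + stats::rnorm(1, 0, 0.08)
      drift <- max(min(drift, 0.22), -0.22)
      dir <- dir + drift
      pos <- pos + stepLen * c(sin(dir), cos(dir))
      total <- total + stepLen
      if (stats::runif(1) < 0.02 && w * cfg@branchDecay >= wmin) {
        # dichotomous branching: two narrower children replace the parent
        split <- stats::runif(1, 0.25, 0.6)
        wc <- w * cfg@branchDecay
        queue[[length(queue) + 1L]] <- list(pos = pos, dir = dir + split, w = wc)
        queue[[length(queue) + 1L]] <- list(pos = pos, dir = dir - split, w = wc)
        break
      }
    }
  }
  invisible(NULL)
}

#' Generate one synthetic fundus image with ground truth
#'
#' Renders branching vessel trees (dark, width-dependent contrast) on a
#' smoothly drifting background inside a circular field of view, adds
#' lesion-like bright/dark blobs that are \emph{not} part of the ground
#' truth, and Gaussian noise.  Identical configurations give bit-identical
#' output; the caller's RNG state is untouched.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @return \code{list(image, mask, fov)}: image is an H x W matrix in [0,1],
#'   mask and fov are H x W binary matrices with mask a subset of fov.
#' @export
generateSample <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  H <- config@canvasSize[1]; W <- config@canvasSize[2]
  withSeed(config@seed, {
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    rfov <- 0.47 * min(H, W)
    ys <- matrix(seq_len(H), H, W)
    xs <- matrix(seq_len(W), H, W, byrow = TRUE)
    fov <- ((ys - cy)^2 + (xs - cx)^2 <= rfov^2) * 1

    # background: base level + oriented linear illumination drift
    theta <- stats::runif(1, 0, 2 * pi)
    proj <- (ys - cy) * sin(theta) + (xs - cx) * cos(theta)
    proj <- proj / max(abs(proj))
    bg <- 0.55 + 0.5 * config@illuminationGradient * proj

    # lesion blobs: anisotropic Gaussian bumps, bright or dark
    lesion <- matrix(0, H, W)
    if (config@nLesions > 0) for (i in seq_len(config@nLesions)) {
      ang <- stats::runif(1, 0, 2 * pi)
      rr <- stats::runif(1, 0, 0.7 * rfov)
      ly <- cy + rr * sin(ang); lx <- cx + rr * cos(ang)
      a <- stats::runif(1, 4, 14); b <- stats::runif(1, 4, 14)
      amp <- sample(c(-1, 1), 1) * stats::runif(1, 0.10, 0.25)
      d2 <- ((ys - ly) / a)^2 + ((xs - lx) / b)^2
      lesion <- lesion + amp * exp(-d2)
    }

    mask <- matrix(0, H, W)
    profile <- matrix(0, H, W)
    if (config@nTrees > 0) for (t in seq_len(config@nTrees)) {
      growTree(mask, profile, cx, cy, rfov, config)
    }
    mask <- mask * fov

    noise <- matrix(stats::rnorm(H * W, 0, config@noiseSd), H, W)
    img <- bg + lesion - profile + noise
    img <- pmin(pmax(img, 0), 1)
    img[fov == 0] <- pmin(img[fov == 0], 0.05)  # dark border outside the FOV
    list(image = img, mask = mask, fov = fov)
  })
}

#' Generate a reproducible synthetic dataset
#'
#' The i-th sample is generated with seed \code{config@seed + i - 1}, so
#' per-sample randomness is disjoint and any sample can be regenerated in
#' isolation.
#'
#' @param nImages number of samples (>= 1).
#' @param config a \linkS4class{SynthConfig}; its seed is the base seed.
#' @return list of \code{list(image, mask, fov)} triples.
#' @export
generateDataset <- function(nImages, config) {
  if (nImages < 1) stop("nImages must be >= 1")
  lapply(seq_len(nImages) - 1L, function(i) {
    cfg <- config
    cfg@seed <- config@seed + i
    generateSample(cfg)
  })
}

#' Write a sample set to disk
#'
#' Images are written as 8-bit grayscale PNG, masks and FOV masks as
#' single-channel PNG with values \{0, 255\}, using the naming scheme
#' \code{<stem>.png}, \code{<stem>_mask.png}, \code{<stem>_fov.png}.
#'
#' @param samples list of triples from [generateDataset()].
#' @param dir output directory (created if missing).
#' @param stem filename stem prefix; samples are numbered \code{stem_001} ...
#' @return invisibly, the vector of image file paths.
#' @export
writeSampleSet <- function(samples, dir, stem = "synth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    base <- file.path(dir, sprintf("%s_%03d", stem, i))
    png::writePNG(s$image, paste0(base, ".png"))
    png::writePNG(s$mask, paste0(base, "_mask.png"))
    png::writePNG(s$fov, paste0(base, "_fov.png"))
    paths[i] <- paste0(base, ".png")
  }
  invisible(paths)
}

#' Read a sample set written by [writeSampleSet()]
#'
#' @param dir directory containing \code{<stem>.png} triples.
#' @return list of \code{list(image, mask, fov, stem)} entries; fov defaults
#'   to all-ones when no \code{_fov.png} exists.
#' @export
readSampleSet <- function(dir) {
  imgs <- list.files(dir, pattern = "\\.(png|tif|tiff|jpg|jpeg|ppm|pgm)$",
                     full.names = TRUE)
  imgs <- imgs[!grepl("_(mask|fov|prob|pred)\\.", imgs)]
  if (length(imgs) == 0) stop("no images found in ", dir)
  lapply(imgs, function(f) {
    stem <- sub("\\.[^.]+$", "", f)
    img <- readImageFile(f)
    maskFile <- list.files(dirname(f), pattern = paste0("^", basename(stem), "_mask\\."),
                           full.names = TRUE)
    fovFile <- list.files(dirname(f), pattern = paste0("^", basename(stem), "_fov\\."),
                          full.names = TRUE)
    mask <- if (length(maskFile)) (readImageFile(maskFile[1]) > 0.5) * 1 else NULL
    fov <- if (length(fovFile)) (readImageFile(fovFile[1]) > 0.5) * 1 else
      matrix(1, nrow(img), ncol(img))
    list(image = img, mask = mask, fov = fov, stem = basename(stem))
  })
}
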
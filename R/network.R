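# The multi-path segmentation network: a 5-level structural U-branch and a
# 3-level texture U-branch over one shared encoder, cascade dilated
# convolution modules (CDCM) in the deeper encoder stages,
# probability-distribution attention (PDA) at the decoder skip junctions,
# and a 4-level U-shaped feature-refinement module consuming the source
# image together with both branch probability maps, with skip connections
# from the structural decoder into the refinement encoder.

#' Create a network architecture specification
#'
#' @param inChannels input image channels (1).
#' @param nClasses output classes C (2: background, vessel).
#' @param baseChannels first-stage channel width F; widths double per level.
#' @param growthRate dense growth rate k inside each CDCM.
#' @param dilationRates dilation rates of the cascaded 3x3 convolutions.
#' @param dropoutRate dropout probability inside CBRD layers.
#' @param useTextureBranch,useCDCM,usePDA,useBoostSupervision ablation
#'   toggles; all on by default (the full model).
#' @return A \linkS4class{NetworkSpec}.
#' @export
networkSpec <- function(inChannels = 1L, nClasses = 2L, baseChannels = 16L,
                        growthRate = 16L, dilationRates = c(1L, 3L, 5L),
                        dropoutRate = 0.2, useTextureBranch = TRUE,
                        useCDCM = TRUE, usePDA = TRUE,
                        useBoostSupervision = TRUE) {
  new("NetworkSpec", inChannels = as.integer(inChannels),
      nClasses = as.integer(nClasses), baseChannels = as.integer(baseChannels),
      growthRate = as.integer(growthRate), encoderDepthStructural = 5L,
      encoderDepthTexture = 3L, refinementDepth = 4L,
      dilationRates = as.integer(dilationRates), dropoutRate = dropoutRate,
      useTextureBranch = useTextureBranch, useCDCM = useCDCM, usePDA = usePDA,
      useBoostSupervision = useBoostSupervision)
}

setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf(
    "NetworkSpec: F=%d k=%d C=%d dilations=(%s) dropout=%.2f [texture=%s cdcm=%s pda=%s boost=%s]\n",
    object@baseChannels, object@growthRate, object@nClasses,
    paste(object@dilationRates, collapse = ","), object@dropoutRate,
    object@useTextureBranch, object@useCDCM, object@usePDA,
    object@useBoostSupervision))
})

# CDCM ------------------------------------------------------------------------

#' Build a cascade dilated convolution module
#'
#' Three densely connected layers, each a CBR bottleneck (1x1 conv + batch
#' norm + ReLU) followed by a CBRD dilated stage (3x3 dilated conv + batch
#' norm + ReLU + dropout) producing \code{growth} new feature maps.  Layer l
#' consumes the concatenation of the block input and all previous layers'
#' new maps, so its input width is F + (l-1) k.  The input and the three
#' outputs (four feature groups) are concatenated and fused by a 1x1
#' projection back to F channels, preserving shape.  The cascaded rates
#' (1, 3, 5) give a 19x19 receptive field: 1 + 2 (1 + 3 + 5).
#'
#' @param channels input/output channel count F.
#' @param growth new maps per dense layer k.
#' @param dilations strictly increasing dilation rates.
#' @param dropout dropout rate inside CBRD.
#' @return an opaque block object for [cdcmForward()].
#' @export
cdcmBlock <- function(channels, growth = 16L, dilations = c(1L, 3L, 5L),
                      dropout = 0.2) {
  nl <- length(dilations)
  layers <- vector("list", nl)
  inCh <- integer(nl)
  for (l in seq_len(nl)) {
    inCh[l] <- channels + (l - 1L) * growth
    layers[[l]] <- list(cbr = newCBR(inCh[l], 2L * growth),
                        cbrd = newCBRD(2L * growth, growth, dilations[l], dropout))
  }
  list(kind = "cdcm", layers = layers, inputChannels = inCh,
       fuse = newCBR(channels + nl * growth, channels),
       channels = channels, growth = growth, dilations = dilations)
}

#' Channel widths seen by the dense layers of a CDCM
#'
#' @param block a [cdcmBlock()].
#' @return integer vector: input channel count of each internal layer,
#'   F + (l-1) k.
#' @export
cdcmLayerChannels <- function(block) block$inputChannels

fwdCDCM <- function(blk, x, training) {
  cur <- x
  for (l in seq_along(blk$layers)) {
    h <- fwdCBR(blk$layers[[l]]$cbr, cur, training)
    h <- fwdCBRD(blk$layers[[l]]$cbrd, h, training)
    cur <- opConcat(list(cur, h))
  }
  fwdCBR(blk$fuse, cur, training)
}

#' Run a CDCM on a feature array
#'
#' @param block a [cdcmBlock()].
#' @param x feature array (H, W, F) or (H, W, F, N).
#' @param training logical; enables batch statistics and dropout.
#' @return array of the same shape as \code{x}.
#' @export
cdcmForward <- function(block, x, training = FALSE) {
  y <- agVal(fwdCDCM(block, pubToInt(x), training))
  intToPub(y, like = x)
}

#' Gradient-probe receptive field of a block
#'
#' Backpropagates from one centre output activation to the input and
#' measures the bounding box of non-zero input gradient: the effective
#' receptive field of the block.
#'
#' @param block a [cdcmBlock()].
#' @param inputSize spatial size of the probe input (odd, comfortably larger
#'   than the expected field).
#' @return integer(2): height and width of the non-zero gradient window.
#' @export
cdcmReceptiveField <- function(block, inputSize = c(41L, 41L)) {
  H <- inputSize[1]; W <- inputSize[2]
  C <- block$channels
  ci <- (H + 1L) %/% 2L; cj <- (W + 1L) %/% 2L
  on.exit(stopTape())
  # a rectifier can silence the probed activation for one particular input;
  # redraw until the centre pixel is live (almost always the first draw)
  for (try in 1:25) {
    x <- array(stats::rnorm(H * W * C), c(H, W, 1L, C))
    startTape()
    xt <- agLeaf(x)
    y <- fwdCDCM(block, xt, FALSE)
    # scalar probe: sum over channels of the centre output pixel
    probe <- agNode(sum(y$v[ci, cj, 1L, ]), list(y), function(g) {
      d <- array(0, dim(y$v))
      d[ci, cj, 1L, ] <- g
      list(d)
    })
    gx <- backwardFromNode(probe, wrt = list(xt))[[1]]
    stopTape()
    nz <- which(apply(abs(gx) > 1e-12, c(1, 2), any), arr.ind = TRUE)
    if (nrow(nz) > 0)
      return(c(diff(range(nz[, 1])) + 1L, diff(range(nz[, 2])) + 1L))
  }
  stop("no live activation found at the probe pixel")
}

# forwardPass helpers ---------------------------------------------------------

# PDA -------------------------------------------------------------------------

#' Build a probability-distribution attention block
#'
#' Holds the learned 1x1 projection K that maps the concatenated
#' class-attended skip stacks (C x skipChannels maps) back to the deep
#' feature width.
#'
#' @param channels channel count of the deep features F.
#' @param skipChannels channel count of the skip features f_i.
#' @param nClasses number of classes C in the shallow logits.
#' @return an opaque block object for [pdaForward()].
#' @export
pdaBlock <- function(channels, skipChannels, nClasses = 2L) {
  list(kind = "pda", K = newConv(1L, 1L, nClasses * skipChannels, channels),
       channels = channels, skipChannels = skipChannels,
       nClasses = as.integer(nClasses))
}

fwdPDA <- function(blk, deep, logits, skip, training) {
  soft <- opSoftmax(logits)
  att <- vector("list", blk$nClasses)
  for (k in seq_len(blk$nClasses)) {
    plane <- opSliceChannel(soft, k)
    att[[k]] <- opScaleChannels(skip, plane)
  }
  proj <- fwdConv(blk$K, opConcat(att))
  opAdd(deep, proj)
}

#' Apply probability-distribution attention
#'
#' The shallow logits F' are softmax-transformed into per-pixel class
#' probability planes; each plane reweights the skip features f_i
#' element-wise, the C attended stacks are concatenated and projected by
#' the learned 1x1 kernel K, and the result is added to the deep features
#' F.  With \code{enabled = FALSE} the deep features are returned exactly
#' (ablation bypass).
#'
#' @param block a [pdaBlock()].
#' @param deep deep feature array F (H, W, channels[, N]).
#' @param logits shallow logits F' (H, W, C[, N]).
#' @param skip skip feature array f_i (H, W, skipChannels[, N]).
#' @param enabled logical bypass toggle.
#' @return array with the geometry of \code{deep}.
#' @export
pdaForward <- function(block, deep, logits, skip, enabled = TRUE) {
  if (!enabled) return(deep)
  y <- agVal(fwdPDA(block, pubToInt(deep), pubToInt(logits), pubToInt(skip),
                    FALSE))
  intToPub(y, like = deep)
}

#' Per-pixel class probabilities from logits
#'
#' Channel softmax: each pixel's class scores are mapped onto the
#' probability simplex.
#'
#' @param logits array (H, W, C) or (H, W, C, N).
#' @return array of the same shape; class planes sum to 1 at every pixel.
#' @export
softmaxProbability <- function(logits) {
  intToPub(opSoftmax(pubToInt(logits)), like = logits)
}

# decoder stage ----------------------------------------------------------------

newUpStage <- function(cin, cout, skipCh, nClasses, usePDA) {
  st <- list(kind = "upstage", up = newConvT(cin, cout),
             conv = newDoubleConv(cout + skipCh, cout), usePDA = usePDA)
  if (usePDA) {
    st$logits <- newConv(1L, 1L, cout, nClasses)
    st$pda <- pdaBlock(cout, skipCh, nClasses)
  }
  st
}

fwdUpStage <- function(st, x, skip, training) {
  u <- fwdConvT(st$up, x)
  if (isTRUE(st$usePDA)) {
    fprime <- fwdConv(st$logits, u)
    u <- fwdPDA(st$pda, u, fprime, skip, training)
  }
  fwdDoubleConv(st$conv, opConcat(list(u, skip)), training)
}

# network assembly -------------------------------------------------------------

#' Build the multi-path segmentation network
#'
#' The first encoder stage is a 3x3 convolution with F output channels plus
#' a residual block; deeper stages are 2x2 stride-2 downsampling
#' convolutions followed by a CDCM (or a plain double 3x3 block when
#' \code{useCDCM} is off).  The texture branch is a 3-level U-shape whose
#' encoder stages are the \emph{same objects} as structural stages 1-3
#' (weight sharing by storage identity).  Decoder stages upsample with 3x3
#' stride-2 transposed convolutions and apply PDA at each skip junction.
#' The refinement module is a 4-level U-shape over the concatenation of the
#' source image and both branch probability maps, with skip connections
#' from the structural decoder at matching scales.  All outputs pass
#' through a channel softmax.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @return A \linkS4class{VesselNet}.
#' @export
buildNetwork <- function(spec = networkSpec()) {
  stopifnot(is(spec, "NetworkSpec"))
  validObject(spec)
  F0 <- spec@baseChannels
  k <- spec@growthRate
  C <- spec@nClasses
  ch <- F0 * 2L^(0:4)
  net <- new.env(parent = emptyenv())

  stageBlock <- function(width) {
    if (spec@useCDCM) cdcmBlock(width, k, spec@dilationRates, spec@dropoutRate)
    else newDoubleConv(width, width)
  }

  # shared encoder (structural stages 1-5; texture aliases stages 1-3)
  net$enc1conv <- newConv(3L, 3L, spec@inChannels, ch[1])
  net$enc1bn <- newBN(ch[1])
  net$enc1res <- newResidual(ch[1])
  net$down <- lapply(2:5, function(l) newDown(ch[l - 1], ch[l]))
  net$stage <- lapply(2:5, function(l) stageBlock(ch[l]))

  # structural decoder
  net$sdec <- lapply(1:4, function(s)
    newUpStage(ch[6 - s], ch[5 - s], ch[5 - s], C, spec@usePDA))
  net$structHead <- newConv(1L, 1L, ch[1], C)
  net$auxLowerHead <- newConv(1L, 1L, ch[3], C)   # after decoder stage 2 (1/4 res)
  net$auxMiddleHead <- newConv(1L, 1L, ch[2], C)  # after decoder stage 3 (1/2 res)

  # texture decoder (2 up-stages from encoder level 3)
  if (spec@useTextureBranch) {
    net$tdec <- list(newUpStage(ch[3], ch[2], ch[2], C, spec@usePDA),
                     newUpStage(ch[2], ch[1], ch[1], C, spec@usePDA))
    net$texHead <- newConv(1L, 1L, ch[1], C)
  }

  # refinement module: 4-level U over concat(image, branch probability maps)
  refIn <- spec@inChannels + C + if (spec@useTextureBranch) C else 0L
  net$refInChannels <- refIn
  net$renc <- list(newDoubleConv(refIn + ch[1], ch[1]),
                   newDoubleConv(ch[2] + ch[2], ch[2]),
                   newDoubleConv(ch[3] + ch[3], ch[3]),
                   newDoubleConv(ch[4] + ch[4], ch[4]))
  net$rdown <- list(newDown(ch[1], ch[2]), newDown(ch[2], ch[3]),
                    newDown(ch[3], ch[4]))
  net$rdec <- list(newUpStage(ch[4], ch[3], ch[3], C, FALSE),
                   newUpStage(ch[3], ch[2], ch[2], C, FALSE),
                   newUpStage(ch[2], ch[1], ch[1], C, FALSE))
  net$refHead <- newConv(1L, 1L, ch[1], C)

  net$all <- list(net$enc1conv, net$enc1bn, net$enc1res, net$down, net$stage,
                  net$sdec, net$structHead, net$auxLowerHead, net$auxMiddleHead,
                  if (spec@useTextureBranch) net$tdec,
                  if (spec@useTextureBranch) net$texHead,
                  net$renc, net$rdown, net$rdec, net$refHead)
  new("VesselNet", spec = spec, net = net)
}

setMethod("show", "VesselNet", function(object) {
  cat(sprintf("VesselNet: F=%d, C=%d, %d trainable parameters\n",
              object@spec@baseChannels, object@spec@nClasses,
              countParams(object)))
})

#' Trainable parameters of a network
#'
#' @param model a \linkS4class{VesselNet}.
#' @return list of parameter environments (each with \code{$v} value and
#'   \code{$grad}); shared parameters appear once.
#' @export
networkParams <- function(model) collectParams(model@net$all)

#' @rdname networkParams
#' @return \code{countParams()}: total number of scalar parameters.
#' @export
countParams <- function(model) {
  sum(vapply(networkParams(model), function(p) length(p$v), numeric(1)))
}

#' Encoder-stage parameters by branch
#'
#' The texture branch aliases structural encoder stages 1-3, so the
#' returned parameter environments for those stages are the identical
#' objects for both branches.
#'
#' @param model a \linkS4class{VesselNet}.
#' @param branch \code{"structural"} or \code{"texture"}.
#' @param stage encoder stage (1-5 structural, 1-3 texture).
#' @return list of parameter environments of that stage.
#' @export
encoderStageParams <- function(model, branch = c("structural", "texture"),
                               stage = 1L) {
  branch <- match.arg(branch)
  net <- model@net
  maxStage <- if (branch == "texture") 3L else 5L
  if (stage < 1L || stage > maxStage) stop("invalid stage for branch ", branch)
  obj <- if (stage == 1L) list(net$enc1conv, net$enc1bn, net$enc1res)
         else list(net$down[[stage - 1L]], net$stage[[stage - 1L]])
  collectParams(obj)
}

# full forward ------------------------------------------------------------------

forwardInternal <- function(model, x, training) {
  spec <- model@spec
  net <- model@net

  e1 <- fwdResidual(net$enc1res,
                    opRelu(fwdBN(net$enc1bn, fwdConv(net$enc1conv, x), training)),
                    training)
  enc <- list(e1)
  for (l in 2:5) {
    h <- fwdDown(net$down[[l - 1]], enc[[l - 1]], training)
    h <- if (spec@useCDCM) fwdCDCM(net$stage[[l - 1]], h, training)
         else fwdDoubleConv(net$stage[[l - 1]], h, training)
    enc[[l]] <- h
  }

  # structural decoder with auxiliary deep-supervision taps
  d <- enc[[5]]
  dFeats <- vector("list", 4L)
  for (s in 1:4) {
    d <- fwdUpStage(net$sdec[[s]], d, enc[[5 - s]], training)
    dFeats[[s]] <- d
  }
  structLogits <- fwdConv(net$structHead, dFeats[[4]])
  structProbs <- opSoftmax(structLogits)
  auxLower <- opUpsample(opSoftmax(fwdConv(net$auxLowerHead, dFeats[[2]])), 4L)
  auxMiddle <- opUpsample(opSoftmax(fwdConv(net$auxMiddleHead, dFeats[[3]])), 2L)

  texProbs <- NULL
  if (spec@useTextureBranch) {
    td <- fwdUpStage(net$tdec[[1]], enc[[3]], enc[[2]], training)
    td <- fwdUpStage(net$tdec[[2]], td, enc[[1]], training)
    texProbs <- opSoftmax(fwdConv(net$texHead, td))
  }

  # refinement: image + branch probability maps, skips from the structural
  # decoder at matching scales into the refinement encoder
  refIn <- if (is.null(texProbs)) opConcat(list(x, structProbs))
           else opConcat(list(x, structProbs, texProbs))
  r1 <- fwdDoubleConv(net$renc[[1]], opConcat(list(refIn, dFeats[[4]])), training)
  r2 <- fwdDoubleConv(net$renc[[2]],
                      opConcat(list(fwdDown(net$rdown[[1]], r1, training), dFeats[[3]])),
                      training)
  r3 <- fwdDoubleConv(net$renc[[3]],
                      opConcat(list(fwdDown(net$rdown[[2]], r2, training), dFeats[[2]])),
                      training)
  r4 <- fwdDoubleConv(net$renc[[4]],
                      opConcat(list(fwdDown(net$rdown[[3]], r3, training), dFeats[[1]])),
                      training)
  u <- fwdUpStage(net$rdec[[1]], r4, r3, training)
  u <- fwdUpStage(net$rdec[[2]], u, r2, training)
  u <- fwdUpStage(net$rdec[[3]], u, r1, training)
  refinedProbs <- opSoftmax(fwdConv(net$refHead, u))

  list(refined = refinedProbs, structural = structProbs, texture = texProbs,
       auxLower = auxLower, auxMiddle = auxMiddle)
}

#' Run the network on a batch of images
#'
#' @param model a \linkS4class{VesselNet}.
#' @param images H x W matrix, (H, W, N) array or (H, W, 1, N) array; H and
#'   W must be divisible by 16 (four 2x downsamplings).
#' @param training logical; batch statistics and dropout when TRUE.
#'   Evaluation mode is deterministic.
#' @return list of probability arrays (H, W, C, N): \code{refined} (the
#'   headline output), \code{structural}, \code{texture} (NULL when the
#'   branch is off) and \code{decoderAux} (lower, middle, output maps at
#'   input resolution).
#' @export
forwardPass <- function(model, images, training = FALSE) {
  stopifnot(is(model, "VesselNet"))
  d <- dim(images)
  x <- if (length(d) == 2L) array(images, c(d, 1L, 1L))
       else if (length(d) == 3L) array(images, c(d, 1L))
       else stop("images must be H x W or (H, W, N)")
  if (any(dim(x)[1:2] %% 16L != 0L))
    stop("input spatial dimensions must be divisible by 16")
  out <- forwardInternal(model, x, training)
  pub <- function(t) intToPub(agVal(t))
  list(refined = pub(out$refined), structural = pub(out$structural),
       texture = if (!is.null(out$texture)) pub(out$texture),
       decoderAux = list(lower = pub(out$auxLower),
                         middle = pub(out$auxMiddle),
                         output = pub(out$structural)))
}

#' Vessel-probability map from network outputs
#'
#' @param outputs result of [forwardPass()].
#' @param which which output map to take (default \code{"refined"}).
#' @return H x W matrix (single image) or (H, W, N) array of vessel-class
#'   probabilities.
#' @export
vesselProbability <- function(outputs, which = "refined") {
  p <- outputs[[which]]
  v <- p[, , 2L, , drop = FALSE]
  if (dim(v)[4] == 1L) matrix(v, dim(p)[1], dim(p)[2])
  else array(v, dim(p)[c(1, 2, 4)])
}
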
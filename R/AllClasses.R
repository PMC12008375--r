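#' @import methods
NULL

#' Configuration for the synthetic fundus-image generator
#'
#' Describes the study conditions emulated by [generateSample()]: the number
#' and geometry of branching vessel trees, the contrast between vessels and
#' background, background illumination drift, additive noise and lesion-like
#' distractor blobs.
#'
#' @slot canvasSize integer(2); image height and width in pixels (>= 64).
#' @slot nTrees integer; number of vessel root stems.
#' @slot branchDecay numeric in (0,1); per-branching-level width shrink factor.
#' @slot minWidth,maxWidth numeric; vessel stem widths in pixels.
#' @slot contrastRange numeric(2) in [0,1]; vessel-vs-background intensity gap,
#'   sampled per tree.
#' @slot nLesions integer; number of bright/dark elliptical lesion blobs
#'   (never added to the ground-truth mask).
#' @slot illuminationGradient numeric in [0,1]; peak-to-peak background drift.
#' @slot noiseSd numeric >= 0; standard deviation of additive Gaussian noise.
#' @slot seed integer RNG seed; identical configurations give identical output.
#' @exportClass SynthConfig
setClass("SynthConfig", representation(
  canvasSize = "integer", nTrees = "integer", branchDecay = "numeric",
  minWidth = "numeric", maxWidth = "numeric", contrastRange = "numeric",
  nLesions = "integer", illuminationGradient = "numeric", noiseSd = "numeric",
  seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@canvasSize) != 2L || any(object@canvasSize < 64L))
      msg <- c(msg, "canvasSize must be two integers >= 64")
    if (object@nTrees < 0L) msg <- c(msg, "nTrees must be >= 0")
    if (!(object@branchDecay > 0 && object@branchDecay < 1))
      msg <- c(msg, "branchDecay must lie in (0,1)")
    if (!(object@minWidth > 0 && object@minWidth <= object@maxWidth))
      msg <- c(msg, "need 0 < minWidth <= maxWidth")
    if (length(object@contrastRange) != 2L || any(object@contrastRange < 0) ||
        any(object@contrastRange > 1) || diff(object@contrastRange) < 0)
      msg <- c(msg, "contrastRange must be an increasing pair in [0,1]")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Configuration for the preprocessing pipeline
#'
#' @slot claheClipLimit positive numeric; CLAHE contrast clip limit on
#'   8-bit-equivalent tile histograms.
#' @slot claheTileGrid integer(2); number of tile rows and columns (>= 2).
#' @slot normalizationMode character; \code{"zscore_rescale"} (standardise,
#'   then rescale to [0,1]) or \code{"minmax"}.
#' @exportClass PreprocessConfig
setClass("PreprocessConfig", representation(
  claheClipLimit = "numeric", claheTileGrid = "integer",
  normalizationMode = "character"),
  validity = function(object) {
    msg <- character()
    if (object@claheClipLimit <= 0) msg <- c(msg, "claheClipLimit must be > 0")
    if (length(object@claheTileGrid) != 2L || any(object@claheTileGrid < 2L))
      msg <- c(msg, "claheTileGrid must be two integers >= 2")
    if (!object@normalizationMode %in% c("zscore_rescale", "minmax"))
      msg <- c(msg, "normalizationMode must be 'zscore_rescale' or 'minmax'")
    if (length(msg)) msg else TRUE
  })

#' An ordered set of image patches with their source coordinates
#'
#' Produced by [extractGrid()] and [samplePatches()]; consumed by
#' [stitchGrid()], which reassembles a full canvas by per-pixel averaging of
#' overlapping patches.
#'
#' @slot patches list of patch arrays (h x w, or h x w x C).
#' @slot coords integer matrix (n x 2) of 0-based (row, col) top-left source
#'   positions.
#' @slot canvasSize integer(2); source canvas height and width.
#' @slot patchSize integer(2); patch height and width.
#' @exportClass PatchGrid
setClass("PatchGrid", representation(
  patches = "list", coords = "matrix", canvasSize = "integer",
  patchSize = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@patches) != nrow(object@coords))
      msg <- c(msg, "patches and coords must have equal length")
    if (nrow(object@coords) > 0) {
      if (any(object@coords < 0L) ||
          any(object@coords[, 1] + object@patchSize[1] > object@canvasSize[1]) ||
          any(object@coords[, 2] + object@patchSize[2] > object@canvasSize[2]))
        msg <- c(msg, "every patch must fit inside the canvas")
    }
    if (length(msg)) msg else TRUE
  })

#' Architectural configuration of the segmentation network
#'
#' @slot inChannels integer; input image channels (1 for grayscale).
#' @slot nClasses integer; output classes C (2: background/vessel).
#' @slot baseChannels integer; channel width F of the first encoder stage;
#'   widths double per level (F, 2F, 4F, 8F, 16F).
#' @slot growthRate integer; new feature maps k added per dense layer inside a
#'   cascade dilated convolution module.
#' @slot encoderDepthStructural,encoderDepthTexture integer; 5 and 3.
#' @slot refinementDepth integer; 4.
#' @slot dilationRates integer(3); strictly increasing dilation rates of the
#'   cascaded 3x3 convolutions (1, 3, 5).
#' @slot dropoutRate numeric in [0,1); dropout inside CBRD layers.
#' @slot useTextureBranch,useCDCM,usePDA,useBoostSupervision logical ablation
#'   toggles.
#' @exportClass NetworkSpec
setClass("NetworkSpec", representation(
  inChannels = "integer", nClasses = "integer", baseChannels = "integer",
  growthRate = "integer", encoderDepthStructural = "integer",
  encoderDepthTexture = "integer", refinementDepth = "integer",
  dilationRates = "integer", dropoutRate = "numeric",
  useTextureBranch = "logical", useCDCM = "logical", usePDA = "logical",
  useBoostSupervision = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@encoderDepthStructural != 5L) msg <- c(msg, "structural encoder depth must be 5")
    if (object@encoderDepthTexture != 3L) msg <- c(msg, "texture encoder depth must be 3")
    if (object@refinementDepth != 4L) msg <- c(msg, "refinement depth must be 4")
    if (any(diff(object@dilationRates) <= 0))
      msg <- c(msg, "dilation rates must be strictly increasing")
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
      msg <- c(msg, "dropoutRate must lie in [0,1)")
    if (object@baseChannels < 1L || object@growthRate < 1L)
      msg <- c(msg, "baseChannels and growthRate must be positive")
    if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
    if (length(msg)) msg else TRUE
  })

#' Deep-supervision loss configuration
#'
#' @slot beta numeric(3); weights of the lower, middle and output decoder
#'   losses (0.3, 0.3, 0.4).
#' @slot gamma numeric in [0,1]; mixing weight between the refined-output
#'   cross entropy and the weighted decoder losses (0.5).
#' @exportClass LossConfig
setClass("LossConfig", representation(beta = "numeric", gamma = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@beta) != 3L || any(object@beta < 0))
      msg <- c(msg, "beta must be three non-negative weights")
    if (object@gamma < 0 || object@gamma > 1) msg <- c(msg, "gamma must lie in [0,1]")
    if (length(msg)) msg else TRUE
  })

#' Training-loop configuration
#'
#' @slot learningRate numeric; initial learning rate (5e-4).
#' @slot batchSize integer; patches per optimisation step (6).
#' @slot maxEpochs integer; epoch budget (20).
#' @slot earlyStopPatience integer; epochs without a new best validation loss
#'   before training halts (10).
#' @slot seed integer; seeds initialisation, shuffling and augmentation.
#' @slot optimizer character; "adam" (adaptive moment estimation).
#' @exportClass TrainConfig
setClass("TrainConfig", representation(
  learningRate = "numeric", batchSize = "integer", maxEpochs = "integer",
  earlyStopPatience = "integer", seed = "integer", optimizer = "character"),
  validity = function(object) {
    msg <- character()
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
    if (object@earlyStopPatience < 1L) msg <- c(msg, "earlyStopPatience must be >= 1")
    if (!object@optimizer %in% c("adam", "sgd")) msg <- c(msg, "optimizer must be 'adam' or 'sgd'")
    if (length(msg)) msg else TRUE
  })

#' Pixel confusion counts inside the field of view
#'
#' @slot TP,FP,TN,FN numeric; non-negative pixel counts.  Their sum equals the
#'   number of evaluated (FOV) pixels.
#' @exportClass ConfusionCounts
setClass("ConfusionCounts", representation(
  TP = "numeric", FP = "numeric", TN = "numeric", FN = "numeric"),
  validity = function(object) {
    if (any(c(object@TP, object@FP, object@TN, object@FN) < 0))
      "counts must be non-negative" else TRUE
  })

#' Dataset-level segmentation metrics
#'
#' Accuracy, sensitivity, specificity and F1 are computed from pooled pixel
#' counts (micro-averaging); per-image F1 scores are kept alongside.
#'
#' @slot acc,sen,spe,f1,auc numeric scalars in [0,1] (NA when undefined).
#' @slot perImageF1 numeric vector of per-image F1 scores.
#' @slot counts the pooled \linkS4class{ConfusionCounts}.
#' @exportClass MetricsReport
setClass("MetricsReport", representation(
  acc = "numeric", sen = "numeric", spe = "numeric", f1 = "numeric",
  auc = "numeric", perImageF1 = "numeric", counts = "ConfusionCounts"))

#' A fitted stagewise additive (gradient-boosted) regression model
#'
#' Prediction is the additive expansion g(z) = h(z; b0) + sum_k alpha_k
#' h(z; b_k): an initial base learner plus K stages, each fitted by least
#' squares to the negative gradient (residuals) of the loss at the current
#' model, with its expansion coefficient found by scalar line search.
#'
#' @slot initial the initial base learner.
#' @slot stages list of K stages, each \code{list(learner, alpha)}.
#' @slot K integer; number of boosting stages.
#' @slot lossName character; loss the model was fitted under.
#' @exportClass BoostModel
setClass("BoostModel", representation(
  initial = "list", stages = "list", K = "integer", lossName = "character"),
  validity = function(object) {
    if (length(object@stages) != object@K) "length(stages) must equal K" else TRUE
  })

#' A built multi-path segmentation network
#'
#' Holds the \linkS4class{NetworkSpec} and an environment with the layer
#' graph: the shared encoder, structural and texture decoders, auxiliary
#' deep-supervision heads and the feature-refinement module.  Use
#' [forwardPass()] to run it and [networkParams()] / [countParams()] to
#' inspect parameters.
#'
#' @slot spec the \linkS4class{NetworkSpec}.
#' @slot net environment containing the layer graph.
#' @exportClass VesselNet
setClass("VesselNet", representation(spec = "NetworkSpec", net = "environment"))
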
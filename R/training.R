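# Seeded training loop with the published hyperparameters (learning rate
# 5e-4, batch size 6, 20 epochs, early stopping after 10 epochs without a
# new best) over randomly sampled, augmented patches.

#' Create a training configuration
#'
#' @param learningRate initial learning rate (5e-4).
#' @param batchSize patches per optimisation step (6).
#' @param maxEpochs epoch budget (20).
#' @param earlyStopPatience epochs without a new best validation loss before
#'   training halts (10).
#' @param seed integer seed for initialisation, shuffling and augmentation.
#' @param optimizer \code{"adam"} (adaptive moment estimation, default) or
#'   \code{"sgd"}.
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(learningRate = 5e-4, batchSize = 6L, maxEpochs = 20L,
                        earlyStopPatience = 10L, seed = 1L,
                        optimizer = "adam") {
  new("TrainConfig", learningRate = learningRate,
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      earlyStopPatience = as.integer(earlyStopPatience),
      seed = as.integer(seed), optimizer = optimizer)
}

#' Seed every random-number stream used by the package
#'
#' All randomness (weight initialisation, patch sampling, augmentation,
#' dropout, shuffling) flows through R's Mersenne-Twister generator, so one
#' call makes subsequent runs deterministic.
#'
#' @param seed integer seed.
#' @export
setGlobalSeed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  invisible(NULL)
}

# one-hot labels for a batch of binary masks, matching the internal
# channel-last probability layout (H, W, N, C)
batchOneHot <- function(masks, C) {
  d <- dim(masks)  # (H, W, N)
  oh <- array(0, c(d, C))
  for (k in seq_len(C)) oh[, , , k] <- (masks == (k - 1L)) * 1
  oh
}

# One optimisation (or evaluation) step on a batch.  Returns the scalar
# loss; when opt is NULL no gradients are computed.
trainStep <- function(model, xb, yb, lcfg, opt = NULL) {
  spec <- model@spec
  training <- !is.null(opt)
  if (training) startTape()
  on.exit(if (training) stopTape())
  xt <- if (training) agLeaf(xb) else xb
  out <- forwardInternal(model, xt, training)
  oh <- batchOneHot(yb, spec@nClasses)
  ceR <- opPixelCE(out$refined, oh)
  if (spec@useBoostSupervision) {
    g <- lcfg@gamma
    loss <- opScalarComb(list(ceR,
                              opPixelCE(out$auxLower, oh),
                              opPixelCE(out$auxMiddle, oh),
                              opPixelCE(out$structural, oh)),
                         c(g, (1 - g) * lcfg@beta))
  } else {
    loss <- ceR
  }
  if (training) {
    zeroGrad(opt$params)
    backwardFromNode(loss)
    optStep(opt)
  }
  agVal(loss)
}

# stack a list of matrices into (H, W, N)
stackTiles <- function(tiles) {
  d <- dim(tiles[[1]])
  array(unlist(tiles, use.names = FALSE), c(d[1], d[2], length(tiles)))
}

# Sample (and augment) training patches from a list of samples.
buildPatchSet <- function(dataset, patchSize, nPatches, seed, augment = TRUE) {
  per <- ceiling(nPatches / length(dataset))
  xs <- list(); ys <- list()
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    pp <- samplePatches(s$image, s$mask, s$fov, patchSize, per,
                        seed = seed + 101L * i)
    for (j in seq_len(per)) {
      img <- pp$image@patches[[j]]
      msk <- pp$mask@patches[[j]]
      if (augment) {
        a <- augmentPair(img, msk, seed = seed + 7919L * i + j)
        img <- a$image; msk <- a$mask
      }
      xs[[length(xs) + 1L]] <- img
      ys[[length(ys) + 1L]] <- msk
    }
  }
  keep <- seq_len(min(nPatches, length(xs)))
  list(x = xs[keep], y = ys[keep])
}

#' Train a segmentation network
#'
#' Runs the deep-supervised composite loss over randomly sampled, augmented
#' patches with early stopping on the validation loss ("best weights" =
#' lowest validation loss).  Fully reproducible for a fixed
#' \code{config@seed}: data order, weight initialisation, augmentation and
#' dropout all derive from it.
#'
#' @param model a \linkS4class{VesselNet} (its current weights are the
#'   starting point).
#' @param trainSet,valSet non-empty lists of \code{list(image, mask, fov)}
#'   samples.
#' @param config a \linkS4class{TrainConfig}.
#' @param lossCfg a \linkS4class{LossConfig}.
#' @param patchSize training patch size (64).
#' @param patchesPerEpoch patches sampled per epoch.
#' @return list with \code{model} (best weights restored), \code{history}
#'   (data.frame epoch/trainLoss/valLoss) and \code{bestEpoch}.
#' @export
trainNetwork <- function(model, trainSet, valSet, config = trainConfig(),
                         lossCfg = lossConfig(), patchSize = 64L,
                         patchesPerEpoch = 120L) {
  if (length(trainSet) == 0 || length(valSet) == 0)
    stop("training and validation sets must be non-empty")
  setGlobalSeed(config@seed)
  params <- networkParams(model)
  opt <- if (config@optimizer == "sgd") newSGD(params, lr = config@learningRate)
         else newAdam(params, lr = config@learningRate)
  valPatches <- buildPatchSet(valSet, patchSize, max(24L, config@batchSize * 4L),
                              seed = config@seed + 555L, augment = FALSE)
  history <- data.frame(epoch = integer(), trainLoss = numeric(),
                        valLoss = numeric())
  best <- list(loss = Inf, state = NULL, epoch = 0L)
  sinceBest <- 0L
  for (epoch in seq_len(config@maxEpochs)) {
    ps <- buildPatchSet(trainSet, patchSize, patchesPerEpoch,
                        seed = config@seed + 1000L * epoch)
    n <- length(ps$x)
    ord <- withSeed(config@seed + epoch, sample.int(n))
    bs <- config@batchSize
    losses <- numeric(0)
    for (b in seq_len(ceiling(n / bs))) {
      idx <- ord[((b - 1L) * bs + 1L):min(b * bs, n)]
      xb <- stackTiles(ps$x[idx])
      dim(xb) <- c(dim(xb), 1L)  # (H, W, N, 1)
      yb <- stackTiles(ps$y[idx])
      losses <- c(losses, trainStep(model, xb, yb, lossCfg, opt))
    }
    vx <- stackTiles(valPatches$x)
    dim(vx) <- c(dim(vx), 1L)
    vy <- stackTiles(valPatches$y)
    valLoss <- trainStep(model, vx, vy, lossCfg, opt = NULL)
    history <- rbind(history, data.frame(epoch = epoch,
                                         trainLoss = mean(losses),
                                         valLoss = valLoss))
    if (valLoss < best$loss) {
      best <- list(loss = valLoss, state = netState(model), epoch = epoch)
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= config@earlyStopPatience) break
    }
  }
  if (!is.null(best$state)) setNetState(model, best$state)
  list(model = model, history = history, bestEpoch = best$epoch)
}

# checkpointing ----------------------------------------------------------------

netState <- function(model) {
  list(params = lapply(networkParams(model), function(p) p$v),
       bns = lapply(collectBNs(model@net$all), function(e) list(rm = e$rm, rv = e$rv)))
}

setNetState <- function(model, state) {
  ps <- networkParams(model)
  stopifnot(length(ps) == length(state$params))
  for (i in seq_along(ps)) ps[[i]]$v <- state$params[[i]]
  bns <- collectBNs(model@net$all)
  stopifnot(length(bns) == length(state$bns))
  for (i in seq_along(bns)) {
    bns[[i]]$rm <- state$bns[[i]]$rm
    bns[[i]]$rv <- state$bns[[i]]$rv
  }
  invisible(model)
}

specToList <- function(spec) {
  list(inChannels = spec@inChannels, nClasses = spec@nClasses,
       baseChannels = spec@baseChannels, growthRate = spec@growthRate,
       dilationRates = spec@dilationRates, dropoutRate = spec@dropoutRate,
       useTextureBranch = spec@useTextureBranch, useCDCM = spec@useCDCM,
       usePDA = spec@usePDA, useBoostSupervision = spec@useBoostSupervision)
}

listToSpec <- function(x) {
  networkSpec(inChannels = x$inChannels, nClasses = x$nClasses,
              baseChannels = x$baseChannels, growthRate = x$growthRate,
              dilationRates = unlist(x$dilationRates),
              dropoutRate = x$dropoutRate,
              useTextureBranch = x$useTextureBranch, useCDCM = x$useCDCM,
              usePDA = x$usePDA, useBoostSupervision = x$useBoostSupervision)
}

#' Save / load a network checkpoint
#'
#' Weights and batch-norm running statistics are serialised to
#' \code{path}; the architecture is recorded in a JSON sidecar
#' (\code{<path>.spec.json}) so the checkpoint is self-describing and the
#' specification round-trips exactly.
#'
#' @param model a \linkS4class{VesselNet}.
#' @param path checkpoint file path (e.g. \code{model.rds}).
#' @return \code{saveCheckpoint()}: invisibly, \code{path};
#'   \code{loadCheckpoint()}: a rebuilt \linkS4class{VesselNet}.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(spec = specToList(model@spec), state = netState(model)), path)
  jsonlite::write_json(specToList(model@spec), paste0(path, ".spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  model <- buildNetwork(listToSpec(ck$spec))
  setNetState(model, ck$state)
  model
}

#' Whole-image prediction by patching and stitching
#'
#' Extracts an edge-snapped sliding-window grid, runs the network on each
#' patch in evaluation mode and averages overlapping vessel-probability
#' tiles back onto the canvas.
#'
#' @param model a \linkS4class{VesselNet}.
#' @param image preprocessed H x W matrix in [0,1].
#' @param patchSize inference patch size (must be divisible by 16).
#' @param stride window stride; default half the patch size.
#' @param batchSize patches per forward pass.
#' @return H x W matrix of vessel probabilities.
#' @export
predictImage <- function(model, image, patchSize = 64L, stride = NULL,
                         batchSize = 8L) {
  if (is.null(stride)) stride <- patchSize %/% 2L
  grid <- extractGrid(image, patchSize, stride)
  n <- length(grid@patches)
  outTiles <- vector("list", n)
  for (b in seq_len(ceiling(n / batchSize))) {
    idx <- ((b - 1L) * batchSize + 1L):min(b * batchSize, n)
    xb <- stackTiles(grid@patches[idx])
    out <- forwardPass(model, xb)
    v <- out$refined[, , 2L, , drop = FALSE]
    for (j in seq_along(idx)) outTiles[[idx[j]]] <- matrix(v[, , 1L, j],
                                                           dim(v)[1], dim(v)[2])
  }
  stitchGrid(newPatchGrid(outTiles, grid@coords, grid@canvasSize, grid@patchSize))
}

#' Dice overlap between a predicted and a true mask
#'
#' 2TP / (2TP + FP + FN); equals the F1 score of the vessel class.
#'
#' @param pred,truth binary matrices.
#' @return scalar in [0,1].
#' @export
diceScore <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  2 * tp / (2 * tp + sum(pred == 1 & truth == 0) + sum(pred == 0 & truth == 1))
}
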
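# Deep-supervised composite loss: a per-pixel cross entropy on the refined
# output, mixed with beta-weighted cross entropies of the three auxiliary
# decoder outputs.

#' Create a loss configuration
#'
#' @param beta weights of the lower, middle and output decoder losses;
#'   default (0.3, 0.3, 0.4).
#' @param gamma mixing weight between the refined-output cross entropy and
#'   the decoder losses; default 0.5.
#' @return A \linkS4class{LossConfig}.
#' @export
lossConfig <- function(beta = c(0.3, 0.3, 0.4), gamma = 0.5) {
  new("LossConfig", beta = as.numeric(beta), gamma = gamma)
}

# Accept labels as a binary matrix (H x W), an integer class matrix in
# 0..C-1, or an already one-hot (H, W, C[, N]) array; return one-hot with
# the probmap's geometry.
labelsToOneHot <- function(labels, d) {
  ld <- dim(labels)
  if (length(ld) == length(d) && all(ld == d)) return(labels)
  C <- d[3]
  N <- if (length(d) >= 4L) d[4] else 1L
  if (length(ld) == 2L) labels <- array(labels, c(ld, N))
  if (!all(dim(labels)[1:2] == d[1:2]))
    stop("labels geometry does not match the probability map")
  oh <- array(0, c(d[1], d[2], C, N))
  for (k in seq_len(C)) oh[, , k, ] <- (labels == (k - 1L)) * 1
  oh
}

#' Per-pixel cross entropy of a probability map against labels
#'
#' Binary-style cross entropy accumulated over every category and pixel and
#' averaged over categories, pixels and batch, so the value is
#' resolution-independent.  Probabilities are clamped to
#' \code{[eps, 1 - eps]} before the logarithms; a (clamped-)perfect one-hot
#' prediction gives a loss below 1e-6 and a uniform binary prediction gives
#' ln 2.
#'
#' @param probmap (H, W, C) or (H, W, C, N) array of per-pixel class
#'   probabilities.
#' @param labels binary H x W matrix (class 1 = vessel), integer class
#'   matrix, or one-hot array matching \code{probmap}.
#' @param eps clamping constant (1e-7).
#' @return non-negative scalar.
#' @export
pixelCE <- function(probmap, labels, eps = 1e-7) {
  p <- as4d(probmap)
  oh <- labelsToOneHot(labels, dim(p))
  q <- pmin(pmax(p, eps), 1 - eps)
  -sum(oh * log(q) + (1 - oh) * log(1 - q)) / length(q)
}

#' Analytic gradient of [pixelCE()] with respect to the probability map
#'
#' @inheritParams pixelCE
#' @return array with the geometry of \code{probmap}.
#' @export
pixelCEGradient <- function(probmap, labels, eps = 1e-7) {
  p <- as4d(probmap)
  oh <- labelsToOneHot(labels, dim(p))
  q <- pmin(pmax(p, eps), 1 - eps)
  g <- -(oh / q - (1 - oh) / (1 - q)) / length(q)
  g <- g * ((p > eps) & (p < 1 - eps))  # clamped entries are flat
  dim(g) <- dim(probmap)
  g
}

#' Weighted sum of the three auxiliary decoder losses
#'
#' @param auxOutputs list of exactly three probability maps (lower, middle,
#'   output decoder), each already upsampled to the label geometry.
#' @param labels as in [pixelCE()].
#' @param beta numeric(3) decoder weights.
#' @return non-negative scalar sum of beta-weighted cross entropies.
#' @export
decoderLosses <- function(auxOutputs, labels, beta = c(0.3, 0.3, 0.4)) {
  if (length(auxOutputs) != 3L) stop("expected exactly three decoder outputs")
  sum(vapply(seq_len(3L), function(d) beta[d] * pixelCE(auxOutputs[[d]], labels),
             numeric(1)))
}

#' Total deep-supervised loss
#'
#' Convex combination gamma * CE(refined) + (1 - gamma) * sum_d beta_d *
#' CE(decoder_d).
#'
#' @param refinedOutput probability map of the refinement module.
#' @param auxOutputs list of three auxiliary decoder probability maps.
#' @param labels as in [pixelCE()].
#' @param config a \linkS4class{LossConfig}.
#' @return non-negative scalar.
#' @export
totalLoss <- function(refinedOutput, auxOutputs, labels, config = lossConfig()) {
  stopifnot(is(config, "LossConfig"))
  config@gamma * pixelCE(refinedOutput, labels) +
    (1 - config@gamma) * decoderLosses(auxOutputs, labels, config@beta)
}
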
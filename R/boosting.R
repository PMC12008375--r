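# Reference implementation of functional gradient boosting: stagewise
# additive modelling where each stage fits the negative gradient
# (residuals) of the loss by least squares and its expansion coefficient is
# found by scalar line search.  The segmentation network realises the same
# principle architecturally, as deep-supervised cascaded refinement; this
# module houses the equations themselves on small regression problems.

boostLosses <- list(
  squared = list(
    loss = function(t, g) 0.5 * (t - g)^2,
    grad = function(t, g) g - t  # dL/dg; residual r = -(dL/dg) = t - g
  ),
  absolute = list(
    loss = function(t, g) abs(t - g),
    grad = function(t, g) sign(g - t)
  )
)

# base learners ---------------------------------------------------------------

fitStump <- function(z, target) {
  o <- order(z)
  zs <- z[o]; ts <- target[o]
  n <- length(z)
  best <- list(sse = Inf, split = -Inf, left = mean(target), right = mean(target))
  uz <- unique(zs)
  if (length(uz) >= 2) {
    splits <- (uz[-1] + uz[-length(uz)]) / 2
    for (s in splits) {
      li <- z <= s
      ml <- mean(target[li]); mr <- mean(target[!li])
      sse <- sum((target[li] - ml)^2) + sum((target[!li] - mr)^2)
      if (sse < best$sse) best <- list(sse = sse, split = s, left = ml, right = mr)
    }
  }
  list(kind = "stump", split = best$split, left = best$left, right = best$right)
}

fitConstant <- function(z, target) list(kind = "constant", value = mean(target))

fitBase <- function(z, target, family) {
  switch(family, stump = fitStump(z, target), constant = fitConstant(z, target),
         stop("unknown base family: ", family))
}

predictBase <- function(learner, z) {
  switch(learner$kind,
         stump = ifelse(z <= learner$split, learner$left, learner$right),
         constant = rep(learner$value, length(z)),
         stop("unknown learner"))
}

#' Fit a gradient-boosted additive model
#'
#' Builds g(z) stagewise: the initial base learner is fitted to the targets;
#' each subsequent stage fits the residuals (negative loss gradient at the
#' current model) by least squares, and its coefficient alpha_k is found by
#' golden-section line search on [-10, 10] (tolerance 1e-8).
#'
#' @param z numeric predictor vector.
#' @param t numeric target vector (length >= 2).
#' @param K number of boosting stages (>= 0); K = 0 returns the initial
#'   learner alone.
#' @param loss \code{"squared"} (default) or \code{"absolute"}, or a
#'   \code{list(loss = function(t, g), grad = function(t, g))} with
#'   \code{grad} the derivative of the loss in its second argument.
#' @param baseFamily \code{"stump"} (depth-1 regression tree, default) or
#'   \code{"constant"}.
#' @return A \linkS4class{BoostModel}.
#' @examples
#' m <- fitBoost(c(0, 1, 2, 3), c(0, 1, 0, 1), K = 10)
#' boostPredict(m, c(0, 1, 2, 3))
#' @export
fitBoost <- function(z, t, K = 10L, loss = "squared", baseFamily = "stump") {
  if (length(z) != length(t) || length(z) < 2) stop("need n >= 2 paired samples")
  if (K < 0) stop("K must be >= 0")
  if (is.character(loss)) {
    lossName <- loss
    L <- boostLosses[[loss]]
    if (is.null(L)) stop("unknown loss: ", loss)
  } else {
    stopifnot(is.list(loss), is.function(loss$loss), is.function(loss$grad))
    lossName <- "custom"
    L <- loss
  }
  initial <- fitBase(z, t, baseFamily)
  g <- predictBase(initial, z)
  stages <- vector("list", K)
  for (k in seq_len(K)) {
    r <- -L$grad(t, g)                      # residuals: negative gradient
    h <- fitBase(z, r, baseFamily)          # least-squares fit to residuals
    hz <- predictBase(h, z)
    alpha <- stats::optimize(function(a) sum(L$loss(t, g + a * hz)),
                             interval = c(-10, 10), tol = 1e-8)$minimum
    g <- g + alpha * hz
    stages[[k]] <- list(learner = h, alpha = alpha)
  }
  new("BoostModel", initial = initial, stages = stages, K = as.integer(K),
      lossName = lossName)
}

#' Predict from a boosted model
#'
#' Evaluates the additive expansion: initial learner plus the
#' coefficient-weighted sum of all stages.
#'
#' @param model a \linkS4class{BoostModel}.
#' @param z numeric predictor vector.
#' @return numeric predictions.
#' @export
boostPredict <- function(model, z) {
  stopifnot(is(model, "BoostModel"))
  g <- predictBase(model@initial, z)
  for (st in model@stages) g <- g + st$alpha * predictBase(st$learner, z)
  g
}

setMethod("show", "BoostModel", function(object) {
  cat(sprintf("BoostModel: initial %s learner + %d stages (%s loss)\n",
              object@initial$kind, object@K, object@lossName))
})
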
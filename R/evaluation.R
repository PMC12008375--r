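# Pixel-level evaluation: confusion counts inside the field of view,
# accuracy/sensitivity/specificity/F1, threshold-sweep ROC/AUC and
# dataset-level reporting with per-image F1.

#' Pixel confusion counts inside the FOV
#'
#' @param pred,truth binary H x W matrices (1 = vessel).
#' @param fov binary H x W matrix; counts are restricted to \code{fov == 1}.
#'   Defaults to the full canvas.
#' @return A \linkS4class{ConfusionCounts}.
#' @export
confusionCounts <- function(pred, truth, fov = NULL) {
  if (is.null(fov)) fov <- matrix(1, nrow(pred), ncol(pred))
  if (!all(dim(pred) == dim(truth)) || !all(dim(pred) == dim(fov)))
    stop("pred, truth and fov must share geometry")
  vals <- c(pred, truth, fov)
  if (!all(vals %in% c(0, 1))) stop("inputs must be binary (0/1)")
  i <- fov == 1
  p <- pred[i]; t <- truth[i]
  new("ConfusionCounts",
      TP = sum(p == 1 & t == 1), FP = sum(p == 1 & t == 0),
      TN = sum(p == 0 & t == 0), FN = sum(p == 0 & t == 1))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%.0f FP=%.0f TN=%.0f FN=%.0f\n",
              object@TP, object@FP, object@TN, object@FN))
})

#' Segmentation metrics from confusion counts
#'
#' Accuracy (TP+TN)/(TP+TN+FP+FN), sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP) and F1 2TP/(2TP+FP+FN).  A metric whose denominator is zero is
#' reported as NA.
#'
#' @param c a \linkS4class{ConfusionCounts}.
#' @return named numeric vector \code{(acc, sen, spe, f1)}.
#' @export
metricsFromCounts <- function(c) {
  stopifnot(is(c, "ConfusionCounts"))
  tot <- c@TP + c@TN + c@FP + c@FN
  if (tot == 0) stop("all counts are zero")
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  c(acc = sdiv(c@TP + c@TN, tot),
    sen = sdiv(c@TP, c@TP + c@FN),
    spe = sdiv(c@TN, c@TN + c@FP),
    f1 = sdiv(2 * c@TP, 2 * c@TP + c@FP + c@FN))
}

#' Threshold-sweep ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold, computes (FPR, TPR) points and
#' integrates by the trapezoidal rule, which credits ties with one half --
#' equivalent to the pairwise concordance probability P(s+ > s-) + 0.5
#' P(tie).  Constant scores therefore give AUC 0.5.
#'
#' @param scores numeric matrix/vector of vessel-class probabilities.
#' @param truth binary matrix/vector of the same length.
#' @param fov optional binary FOV restriction.
#' @return list with \code{auc} and a two-column \code{roc} matrix of
#'   monotone (fpr, tpr) points.
#' @export
rocAuc <- function(scores, truth, fov = NULL) {
  s <- as.numeric(scores); y <- as.numeric(truth)
  if (!is.null(fov)) {
    keep <- as.numeric(fov) == 1
    s <- s[keep]; y <- y[keep]
  }
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  if (nPos == 0 || nNeg == 0) stop("both classes must be present")
  o <- order(s, decreasing = TRUE)
  ys <- y[o]
  # group tied scores: cumulative counts at each distinct threshold
  dup <- rev(duplicated(rev(s[o])))  # TRUE where the next value is tied
  tp <- cumsum(ys == 1)[!dup]
  fp <- cumsum(ys == 0)[!dup]
  tpr <- c(0, tp / nPos)
  fpr <- c(0, fp / nNeg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc, roc = cbind(fpr = fpr, tpr = tpr))
}

perImageCounts <- function(pred, truth, fov) confusionCounts(pred, truth, fov)

#' Evaluate predicted probability maps over a dataset
#'
#' Dataset-level accuracy/sensitivity/specificity/F1 from pooled pixel
#' counts (micro-averaging) plus the pooled-score AUC; per-image F1 values
#' are reported alongside.  Optionally writes \code{metrics.json},
#' \code{per_image.csv} and \code{roc.csv} to \code{outDir}.
#'
#' @param probs list of vessel-probability matrices (values in [0,1]).
#' @param dataset list of \code{list(image, mask, fov)} samples of matching
#'   geometry.
#' @param threshold binarisation threshold for the confusion-based metrics.
#' @param insideFov logical; restrict evaluation to the FOV (default TRUE,
#'   the standard practice for fundus benchmarks).
#' @param outDir optional report directory.
#' @return A \linkS4class{MetricsReport}.
#' @export
evaluateDataset <- function(probs, dataset, threshold = 0.5, insideFov = TRUE,
                            outDir = NULL) {
  if (length(dataset) == 0) stop("empty dataset")
  if (length(probs) != length(dataset)) stop("one probability map per sample required")
  pooled <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  perF1 <- numeric(length(dataset))
  allScores <- list(); allTruth <- list()
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    fov <- if (insideFov) s$fov else matrix(1, nrow(s$mask), ncol(s$mask))
    pred <- (probs[[i]] >= threshold) * 1
    cc <- confusionCounts(pred, s$mask, fov)
    pooled <- pooled + c(TP = cc@TP, FP = cc@FP, TN = cc@TN, FN = cc@FN)
    perF1[i] <- metricsFromCounts(cc)[["f1"]]
    keep <- fov == 1
    allScores[[i]] <- probs[[i]][keep]
    allTruth[[i]] <- s$mask[keep]
  }
  counts <- new("ConfusionCounts", TP = pooled[["TP"]], FP = pooled[["FP"]],
                TN = pooled[["TN"]], FN = pooled[["FN"]])
  m <- metricsFromCounts(counts)
  roc <- rocAuc(unlist(allScores), unlist(allTruth))
  rep <- new("MetricsReport", acc = m[["acc"]], sen = m[["sen"]],
             spe = m[["spe"]], f1 = m[["f1"]], auc = roc$auc,
             perImageF1 = perF1, counts = counts)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(acc = m[["acc"]], sen = m[["sen"]],
                              spe = m[["spe"]], f1 = m[["f1"]],
                              auc = roc$auc),
                         file.path(outDir, "metrics.json"), auto_unbox = TRUE,
                         digits = NA)
    utils::write.csv(data.frame(image = seq_along(perF1), f1 = perF1),
                     file.path(outDir, "per_image.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(roc$roc), file.path(outDir, "roc.csv"),
                     row.names = FALSE)
  }
  rep
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: acc=%.4f sen=%.4f spe=%.4f f1=%.4f auc=%.4f (%d images)\n",
              object@acc, object@sen, object@spe, object@f1, object@auc,
              length(object@perImageF1)))
})
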
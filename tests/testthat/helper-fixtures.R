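# Shared fixtures for the test suite; everything is generated in code.

# random per-pixel probability map (H, W, C) on the simplex
randomProbMap <- function(H, W, C = 2L) {
  a <- array(stats::runif(H * W * C, 0.05, 1), c(H, W, C))
  s <- apply(a, c(1, 2), sum)
  for (k in seq_len(C)) a[, , k] <- a[, , k] / s
  a
}

randomMask <- function(H, W, p = 0.3) {
  matrix(stats::rbinom(H * W, 1L, p), H, W)
}

# a small preprocessed synthetic sample for network tests
smallSample <- function(seed = 5L, canvas = 128L) {
  s <- generateSample(synthConfig(canvasSize = c(canvas, canvas), seed = seed))
  list(image = preprocessImage(s$image), mask = s$mask, fov = s$fov)
}

tinySpec <- function(...) networkSpec(baseChannels = 8L, growthRate = 8L, ...)

# O(n^2) pairwise-concordance AUC oracle: P(s+ > s-) + 0.5 P(tie)
aucConcordance <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  d <- outer(sp, sn, "-")
  (sum(d > 0) + 0.5 * sum(d == 0)) / (length(sp) * length(sn))
}
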
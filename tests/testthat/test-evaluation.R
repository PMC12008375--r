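test_that("confusion counts agree with a per-pixel loop oracle", {
  set.seed(61)
  for (rep in 1:50) {
    pred <- randomMask(16, 16)
    truth <- randomMask(16, 16)
    fov <- randomMask(16, 16, 0.8)
    cc <- confusionCounts(pred, truth, fov)
    tp <- fp <- tn <- fn <- 0
    for (i in 1:16) for (j in 1:16) if (fov[i, j] == 1) {
      if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1
      if (pred[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1
      if (pred[i, j] == 0 && truth[i, j] == 0) tn <- tn + 1
      if (pred[i, j] == 0 && truth[i, j] == 1) fn <- fn + 1
    }
    expect_identical(c(cc@TP, cc@FP, cc@TN, cc@FN) * 1, c(tp, fp, tn, fn) * 1)
    expect_equal(cc@TP + cc@FP + cc@TN + cc@FN, sum(fov))
  }

  t0 <- randomMask(8, 8)
  agree <- confusionCounts(t0, t0)
  expect_equal(agree@FP + agree@FN, 0)
  inv <- confusionCounts(1 - t0, t0)
  expect_equal(inv@TP + inv@TN, 0)
  expect_error(confusionCounts(t0 * 0.5, t0), "binary")
})

test_that("metric formulas are exact", {
  m <- metricsFromCounts(new("ConfusionCounts", TP = 9, FP = 0, TN = 0, FN = 1))
  expect_equal(m[["sen"]], 0.9)

  m2 <- metricsFromCounts(new("ConfusionCounts", TP = 90, TN = 890, FP = 10, FN = 10))
  expect_equal(m2[["acc"]], 0.98)
  expect_equal(m2[["f1"]], 0.9)

  set.seed(62)
  for (rep in 1:20) {
    k <- as.numeric(sample(0:50, 4, replace = TRUE)) + 1
    cc <- new("ConfusionCounts", TP = k[1], FP = k[2], TN = k[3], FN = k[4])
    m <- metricsFromCounts(cc)
    expect_equal(m[["acc"]], (k[1] + k[3]) / sum(k), tolerance = 1e-12)
    expect_equal(m[["sen"]], k[1] / (k[1] + k[4]), tolerance = 1e-12)
    expect_equal(m[["spe"]], k[3] / (k[3] + k[2]), tolerance = 1e-12)
    expect_equal(m[["f1"]], 2 * k[1] / (2 * k[1] + k[2] + k[4]), tolerance = 1e-12)
    # rational identity: Sen * (TP + FN) = TP
    expect_equal(m[["sen"]] * (k[1] + k[4]), k[1], tolerance = 1e-12)
  }
})

test_that("threshold-sweep AUC equals pairwise concordance with half ties", {
  # perfectly separating scores
  truth <- c(rep(1, 10), rep(0, 10))
  scores <- c(runif(10, 0.6, 1), runif(10, 0, 0.4))
  expect_equal(rocAuc(scores, truth)$auc, 1.0)

  # constant scores: every pair ties
  expect_equal(rocAuc(rep(0.3, 20), truth)$auc, 0.5)

  set.seed(63)
  for (rep in 1:10) {
    s <- round(runif(500), 2)  # rounding forces ties
    y <- rbinom(500, 1, 0.4)
    r <- rocAuc(s, y)
    expect_equal(r$auc, aucConcordance(s, y), tolerance = 1e-9)
    expect_true(all(diff(r$roc[, "fpr"]) >= 0))
    expect_true(all(diff(r$roc[, "tpr"]) >= 0))
  }

  # invariance under strictly monotone transforms of the scores
  s <- runif(300); y <- rbinom(300, 1, 0.5)
  expect_equal(rocAuc(s, y)$auc, rocAuc(exp(3 * s) - 1, y)$auc, tolerance = 1e-12)
  expect_error(rocAuc(s, rep(1, 300)), "both classes")
})

test_that("dataset evaluation pools counts and writes reports", {
  set.seed(64)
  ds <- lapply(1:3, function(i) {
    m <- randomMask(32, 32)
    list(image = matrix(0, 32, 32), mask = m, fov = matrix(1, 32, 32))
  })
  # perfect predictions give all metrics 1
  perfect <- lapply(ds, function(s) s$mask * 0.98 + 0.01)
  rep1 <- evaluateDataset(perfect, ds)
  expect_equal(c(rep1@acc, rep1@sen, rep1@spe, rep1@f1, rep1@auc),
               rep(1, 5))

  # pooled counts equal the sum of per-image counts
  probs <- lapply(ds, function(s) matrix(runif(32 * 32), 32, 32))
  repo <- evaluateDataset(probs, ds)
  sums <- Reduce(`+`, lapply(1:3, function(i) {
    cc <- confusionCounts((probs[[i]] >= 0.5) * 1, ds[[i]]$mask, ds[[i]]$fov)
    c(cc@TP, cc@FP, cc@TN, cc@FN)
  }))
  expect_equal(c(repo@counts@TP, repo@counts@FP, repo@counts@TN, repo@counts@FN),
               sums)
  # binarisation at 0.5 ties the pooled F1 to the counts-based formula
  expect_equal(repo@f1, metricsFromCounts(repo@counts)[["f1"]])

  dir <- withr::local_tempdir()
  evaluateDataset(probs, ds, outDir = dir)
  expect_true(all(file.exists(file.path(dir, c("metrics.json", "per_image.csv", "roc.csv")))))
  js <- jsonlite::read_json(file.path(dir, "metrics.json"))
  expect_equal(js$acc, repo@acc, tolerance = 1e-12)

  expect_error(evaluateDataset(list(), list()), "empty")
})
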
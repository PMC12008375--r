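# Architectural contracts of the multi-path network and its blocks.

test_that("CDCM blocks honour the dense-growth and receptive-field contracts", {
  set.seed(71)
  blk <- cdcmBlock(32L, 16L, c(1L, 3L, 5L), dropout = 0)
  expect_equal(cdcmLayerChannels(blk), c(32L, 48L, 64L))

  x <- array(rnorm(16 * 16 * 32), c(16, 16, 32))
  y <- cdcmForward(blk, x)
  expect_identical(dim(y), dim(x))

  # dense-growth arithmetic F + (l-1) k for other width settings
  expect_equal(cdcmLayerChannels(cdcmBlock(8L, 4L)), c(8L, 12L, 16L))
  expect_equal(cdcmLayerChannels(cdcmBlock(64L, 16L)), c(64L, 80L, 96L))

  # gradient-probe receptive field: 1 + 2 (1 + 3 + 5) = 19
  small <- cdcmBlock(4L, 4L, c(1L, 3L, 5L), dropout = 0)
  expect_equal(cdcmReceptiveField(small, c(31L, 31L)), c(19L, 19L))
})

test_that("PDA satisfies its probability and bypass contracts", {
  set.seed(72)
  blk <- pdaBlock(6L, 4L, 2L)
  Fv <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  Fp <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  sk <- array(rnorm(8 * 8 * 4), c(8, 8, 4))

  soft <- softmaxProbability(Fp)
  expect_lt(max(abs(apply(soft, c(1, 2), sum) - 1)), 1e-6)

  # uniform logits: every class plane is 1/C, so the attended term is the
  # projection of C copies of skip/C; computed directly from K's weights
  Fp0 <- array(0, c(2, 2, 2))
  Fv0 <- array(rnorm(2 * 2 * 6), c(2, 2, 6))
  sk0 <- array(rnorm(2 * 2 * 4), c(2, 2, 4))
  out <- pdaForward(blk, Fv0, Fp0, sk0)
  K <- blk$K
  oracle <- array(0, c(2, 2, 6))
  for (i in 1:2) for (j in 1:2) {
    fca <- c(sk0[i, j, ] / 2, sk0[i, j, ] / 2)  # C = 2 attended stacks
    for (co in 1:6)
      oracle[i, j, co] <- Fv0[i, j, co] + sum(fca * K$w$v[1, 1, , co]) + K$b$v[co]
  }
  expect_lt(max(abs(out - oracle)), 1e-10)

  expect_identical(pdaForward(blk, Fv, Fp, sk, enabled = FALSE), Fv)
})

test_that("the assembled network meets geometry, simplex and sharing contracts", {
  setGlobalSeed(73)
  m <- buildNetwork(tinySpec())
  x <- matrix(runif(64 * 64), 64, 64)
  out <- forwardPass(m, x)
  expect_identical(dim(out$refined), c(64L, 64L, 2L, 1L))
  for (nm in c("refined", "structural", "texture")) {
    p <- out[[nm]]
    expect_identical(dim(p)[1:2], c(64L, 64L))
    expect_lt(max(abs(apply(p, c(1, 2, 4), sum) - 1)), 1e-6)
  }
  for (aux in out$decoderAux) {
    expect_identical(dim(aux)[1:2], c(64L, 64L))
    expect_lt(max(abs(apply(aux, c(1, 2, 4), sum) - 1)), 1e-6)
  }

  # evaluation mode is deterministic
  expect_identical(out, forwardPass(m, x))

  # texture encoder stages alias the structural ones by storage identity
  for (stage in 1:3) {
    a <- encoderStageParams(m, "structural", stage)
    b <- encoderStageParams(m, "texture", stage)
    expect_identical(a, b)
    for (k in seq_along(a)) expect_true(identical(a[[k]], b[[k]]))
  }

  expect_error(forwardPass(m, matrix(0, 60, 60)), "divisible")
})

test_that("shared weights really are one storage location", {
  setGlobalSeed(74)
  m <- buildNetwork(tinySpec())
  p1 <- encoderStageParams(m, "structural", 2)[[1]]
  p2 <- encoderStageParams(m, "texture", 2)[[1]]
  p1$v[1] <- 123
  expect_equal(p2$v[1], 123)  # updating one branch updates the other
})

test_that("ablation toggles keep every output contract intact", {
  setGlobalSeed(75)
  x <- matrix(runif(64 * 64), 64, 64)
  base <- buildNetwork(tinySpec(useTextureBranch = FALSE, useCDCM = FALSE,
                                usePDA = FALSE, useBoostSupervision = FALSE))
  outB <- forwardPass(base, x)
  expect_null(outB$texture)
  expect_lt(max(abs(apply(outB$refined, c(1, 2, 4), sum) - 1)), 1e-6)

  full <- buildNetwork(tinySpec())
  # dropping the texture branch removes C channels from the refinement input
  expect_equal(full@net$refInChannels - base@net$refInChannels, 2L)
})

test_that("every parameter receives gradient on a random batch", {
  setGlobalSeed(76)
  m <- buildNetwork(tinySpec())
  params <- networkParams(m)
  fundusnet:::zeroGrad(params)
  xb <- array(runif(64 * 64 * 2), c(64, 64, 2, 1))
  yb <- array(rbinom(64 * 64 * 2, 1, 0.2), c(64, 64, 2))
  opt <- fundusnet:::newSGD(params, lr = 0)  # accumulate gradients only
  invisible(fundusnet:::trainStep(m, xb, yb, lossConfig(), opt))
  gmax <- vapply(params, function(p) max(abs(p$grad)), numeric(1))
  expect_true(all(gmax > 0))
})

test_that("checkpoints round-trip the specification and the weights", {
  setGlobalSeed(77)
  m <- buildNetwork(tinySpec(usePDA = FALSE))
  path <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(m, path)
  expect_true(file.exists(paste0(path, ".spec.json")))
  m2 <- loadCheckpoint(path)
  expect_equal(m2@spec, m@spec)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_equal(forwardPass(m2, x), forwardPass(m, x), tolerance = 1e-12)
})
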
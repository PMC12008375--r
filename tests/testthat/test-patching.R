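test_that("sliding-window grids enumerate raster positions with edge snap", {
  x <- matrix(runif(128 * 128), 128, 128)
  g <- extractGrid(x, 64L, 32L)
  expect_equal(length(g), 9L)
  expect_setequal(unique(g@coords[, 1]), c(0L, 32L, 64L))
  expect_setequal(unique(g@coords[, 2]), c(0L, 32L, 64L))
  # raster order: rows advance slowest
  expect_equal(g@coords[1:3, 2], c(0L, 32L, 64L))

  one <- extractGrid(matrix(0, 64, 64), 64L, 17L)
  expect_equal(length(one), 1L)
  expect_equal(one@coords[1, ], c(0L, 0L))

  snapped <- extractGrid(matrix(0, 100, 100), 64L, 64L)
  expect_setequal(unique(snapped@coords[, 2]), c(0L, 36L))

  expect_error(extractGrid(matrix(0, 32, 32), 64L), "larger")
})

test_that("grid coverage is complete for any stride up to the patch size", {
  set.seed(31)
  for (i in 1:10) {
    H <- sample(64:150, 1); W <- sample(64:150, 1)
    ps <- sample(c(32L, 48L, 64L), 1)
    st <- sample(seq_len(ps), 1)
    g <- extractGrid(matrix(0, H, W), ps, st)
    covered <- matrix(0L, H, W)
    for (k in seq_len(length(g))) {
      r <- g@coords[k, 1]; c <- g@coords[k, 2]
      covered[r + seq_len(ps), c + seq_len(ps)] <- 1L
    }
    expect_true(all(covered == 1L))
  }
})

test_that("random patch sampling is seeded and FOV-centred", {
  s <- generateSample(synthConfig(canvasSize = c(128L, 128L), seed = 9L))
  a <- samplePatches(s$image, s$mask, s$fov, 32L, 10L, seed = 4L)
  b <- samplePatches(s$image, s$mask, s$fov, 32L, 10L, seed = 4L)
  expect_identical(a$image@coords, b$image@coords)
  expect_identical(a$image@coords, a$mask@coords)
  expect_true(all(unlist(a$mask@patches) %in% c(0, 1)))

  # every patch centre lies inside a centred-disk FOV
  H <- 128; cy <- (H + 1) / 2; r <- 0.47 * H
  many <- samplePatches(s$image, s$mask, s$fov, 32L, 500L, seed = 5L)
  ctr <- many$image@coords + 16  # 0-based top-left + half patch -> 1-based centre
  d <- sqrt((ctr[, 1] + 1 - cy)^2 + (ctr[, 2] + 1 - cy)^2)
  expect_true(all(d <= r + 1))

  fov0 <- matrix(0, 128, 128)
  expect_error(samplePatches(s$image, s$mask, fov0, 32L, 2L, seed = 1L), "FOV")
})

test_that("augmentation applies one joint transform with exact conventions", {
  img <- matrix(runif(16), 4, 4)
  msk <- matrix(0, 4, 4); msk[1, 1] <- 1

  id <- augmentPair(img, msk, seed = 1L, rot90s = FALSE, flips = FALSE)
  expect_identical(id$image, img)
  expect_identical(id$mask, msk)

  # horizontal flip is an involution
  f1 <- img[, 4:1]
  expect_identical(f1[, 4:1], img)

  # one counter-clockwise quarter turn maps (0,0) -> (3,0)
  r <- fundusnet:::rot90ccw(msk)
  expect_equal(which(r == 1, arr.ind = TRUE)[1, ], c(row = 4L, col = 1L))

  # vessel-pixel count is preserved under rotations and flips
  m2 <- randomMask(32, 32)
  i2 <- matrix(runif(32 * 32), 32, 32)
  for (seed in 1:10) {
    out <- augmentPair(i2, m2, seed = seed)
    expect_equal(sum(out$mask), sum(m2))
    expect_true(all(out$mask %in% c(0, 1)))
    expect_identical(dim(out$image), dim(i2))
  }

  # scale jitter keeps geometry and binarises the mask
  sj <- augmentPair(i2, m2, seed = 3L, scaleJitter = c(0.8, 1.2))
  expect_identical(dim(sj$image), dim(i2))
  expect_true(all(sj$mask %in% c(0, 1)))
})

test_that("stitching averages overlaps and inverts extraction", {
  set.seed(33)
  x <- matrix(runif(128 * 128), 128, 128)
  g <- extractGrid(x, 64L, 32L)
  expect_lt(max(abs(stitchGrid(g) - x)), 1e-6)

  # two fully overlapping constant patches average to 0.5
  two <- fundusnet:::newPatchGrid(list(matrix(0, 8, 8), matrix(1, 8, 8)),
                                  rbind(c(0L, 0L), c(0L, 0L)), c(8L, 8L), c(8L, 8L))
  expect_true(all(stitchGrid(two) == 0.5))

  # perturbed tiles match an explicit accumulate/divide oracle
  g2 <- extractGrid(x, 64L, 32L)
  set.seed(34)
  g2@patches <- lapply(g2@patches, function(p) p + rnorm(1))
  acc <- matrix(0, 128, 128); cnt <- matrix(0, 128, 128)
  for (k in seq_len(length(g2))) {
    ri <- g2@coords[k, 1] + 1:64; ci <- g2@coords[k, 2] + 1:64
    acc[ri, ci] <- acc[ri, ci] + g2@patches[[k]]
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  expect_lt(max(abs(stitchGrid(g2) - acc / cnt)), 1e-9)

  # linearity in the patch values
  g3 <- g2; g3@patches <- lapply(g2@patches, function(p) 3 * p)
  expect_lt(max(abs(stitchGrid(g3) - 3 * stitchGrid(g2))), 1e-9)
})
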
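test_that("grayscale conversion uses the BT.601 luminance weights", {
  v <- 0.37
  uni <- array(v, c(5, 5, 3))
  expect_equal(toGrayscale(uni), matrix(v, 5, 5), tolerance = 1e-12)

  green <- array(0, c(4, 4, 3)); green[, , 2] <- 1
  expect_equal(toGrayscale(green), matrix(0.587, 4, 4), tolerance = 1e-12)

  set.seed(21)
  rgb <- array(runif(8 * 8 * 3), c(8, 8, 3))
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    oracle[i, j] <- 0.299 * rgb[i, j, 1] + 0.587 * rgb[i, j, 2] + 0.114 * rgb[i, j, 3]
  expect_lt(max(abs(toGrayscale(rgb) - oracle)), 1e-12)

  expect_error(toGrayscale(matrix(0, 4, 4)), "3")
})

test_that("normalisation rescales to [0,1] and standardises affine families", {
  expect_equal(normalizeImage(matrix(0.8, 6, 6)), matrix(0.5, 6, 6))

  set.seed(22)
  x <- matrix(runif(64), 8, 8)
  for (mode in c("zscore_rescale", "minmax")) {
    y <- normalizeImage(x, mode)
    expect_equal(range(y), c(0, 1))
  }
  # affine intensity transforms collapse to the same output
  y1 <- normalizeImage(x, "zscore_rescale")
  y2 <- normalizeImage(0.4 * x + 0.17, "zscore_rescale")
  expect_lt(max(abs(y1 - y2)), 1e-12)
  # minmax normalisation is idempotent
  m <- normalizeImage(x, "minmax")
  expect_lt(max(abs(normalizeImage(m, "minmax") - m)), 1e-12)
})

test_that("CLAHE preserves geometry, range, and raises local contrast", {
  cfg <- preprocessConfig()
  const <- matrix(0.42, 64, 64)
  expect_identical(claheEnhance(const, cfg), const)

  set.seed(23)
  x <- matrix(runif(256 * 256), 256, 256)
  y <- claheEnhance(x, cfg)
  expect_identical(dim(y), dim(x))
  expect_true(all(y >= 0 & y <= 1))

  # a low-contrast image gains per-tile contrast
  low <- 0.5 + 0.05 * matrix(runif(128 * 128, -1, 1), 128, 128)
  hi <- claheEnhance(low, cfg)
  sdTile <- function(img) {
    vapply(0:3, function(ti) {
      vapply(0:3, function(tj) {
        sd(img[ti * 32 + 1:32, tj * 32 + 1:32])
      }, numeric(1))
    }, numeric(4))
  }
  expect_true(all(sdTile(hi) > sdTile(low)))

  expect_error(claheEnhance(matrix(runif(16), 4, 4), cfg), "tile grid")
})

test_that("the pipeline composes deterministically and stays in [0,1]", {
  set.seed(24)
  # single-channel input skips the grayscale conversion
  g <- matrix(runif(64 * 64), 64, 64)
  p1 <- preprocessImage(g)
  p2 <- preprocessImage(g)
  expect_identical(p1, p2)
  expect_identical(preprocessImage(normalizeImage(g)),
                   claheEnhance(normalizeImage(normalizeImage(g))))

  for (i in 1:20) {
    s <- generateSample(synthConfig(canvasSize = c(64L, 64L), seed = 400L + i))
    out <- preprocessImage(s$image)
    expect_true(all(out >= 0 & out <= 1))
    expect_identical(dim(out), dim(s$image))
  }

  # purity: the input is not mutated
  before <- g + 0
  invisible(preprocessImage(g))
  expect_identical(g, before)
})
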
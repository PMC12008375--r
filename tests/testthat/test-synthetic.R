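# The synthetic fundus generator defines the study conditions for every
# downstream test, so its statistical contracts are pinned down here.

test_that("generation is deterministic and respects basic geometry", {
  cfg <- synthConfig(seed = 3L)
  a <- generateSample(cfg)
  b <- generateSample(cfg)
  expect_identical(a, b)

  expect_true(all(a$mask %in% c(0, 1)))
  expect_true(all(a$fov %in% c(0, 1)))
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_identical(dim(a$image), dim(a$mask))
  expect_identical(dim(a$image), dim(a$fov))
  # mask is a subset of the field of view
  expect_true(all(a$mask[a$fov == 0] == 0))
})

test_that("no trees means an empty mask; tiny canvases are rejected", {
  s <- generateSample(synthConfig(nTrees = 0L, seed = 1L))
  expect_equal(sum(s$mask), 0)
  expect_error(synthConfig(canvasSize = c(32L, 32L)), "canvasSize")
  expect_error(synthConfig(branchDecay = 1.2), "branchDecay")
})

test_that("default configuration hits the vessel-density band", {
  frac <- thin <- numeric(25)
  comps <- integer(25)
  for (i in seq_len(25)) {
    cfg <- synthConfig(seed = 100L + i)
    s <- generateSample(cfg)
    frac[i] <- sum(s$mask) / sum(s$fov)
    dm <- EBImage::imageData(EBImage::distmap(s$mask))
    width <- 2 * dm[s$mask == 1] - 1  # distance-transform width estimate
    thin[i] <- mean(width <= 2)
    comps[i] <- max(EBImage::bwlabel(s$mask))
    # every connected component is (a union of) rooted trees
    expect_lte(comps[i], cfg@nTrees)
  }
  expect_true(all(frac >= 0.03 & frac <= 0.20))
  # at least 10% of vessel pixels lie in branches of width <= 2 px
  expect_true(all(thin >= 0.10))
})

test_that("datasets use disjoint per-sample seeds and are reproducible", {
  cfg <- synthConfig(seed = 40L)
  ds <- generateDataset(5L, cfg)
  expect_length(ds, 5L)
  # first sample equals a direct call at the base seed
  expect_identical(ds[[1]], generateSample(cfg))
  # pairwise distinct masks
  for (i in 1:4) for (j in (i + 1):5)
    expect_false(identical(ds[[i]]$mask, ds[[j]]$mask))
  expect_error(generateDataset(0L, cfg), "nImages")
})

test_that("sample sets round-trip through PNG on disk", {
  dir <- withr::local_tempdir()
  ds <- generateDataset(2L, synthConfig(canvasSize = c(64L, 64L), seed = 8L))
  writeSampleSet(ds, dir)
  expect_length(list.files(dir, pattern = "\\.png$"), 6L)
  back <- readSampleSet(dir)
  expect_length(back, 2L)
  # masks are binary PNGs and survive exactly; images to 8-bit precision
  expect_equal(back[[1]]$mask, ds[[1]]$mask)
  expect_equal(back[[1]]$fov, ds[[1]]$fov)
  expect_lt(max(abs(back[[1]]$image - ds[[1]]$image)), 1 / 255)
})
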
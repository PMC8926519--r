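test_that("phantom config validation names the offending field", {
  expect_error(phantomConfig(imageSize = 50), "imageSize")
  expect_error(phantomConfig(tumorContrast = 1.2), "tumorContrast")
  expect_error(phantomConfig(nTumorsRange = c(3, 1)), "nTumorsRange")
  expect_error(phantomConfig(imageSize = 64, tumorRadiusRange = c(5, 40)),
               "tumorRadiusRange")
})

test_that("a no-tumor configuration yields an absent sample with empty mask", {
  cfg <- tinyPhantomConfig(nTumorsRange = c(0L, 0L))
  s <- makePhantom(cfg, seed = 1)
  expect_identical(sampleClass(s), "absent")
  expect_true(all(normalLabel(s) == 0L))
  expect_true(all(boundaryLabel(s) == 0L))
})

test_that("phantom generation is bit-identical for a fixed config and seed", {
  cfg <- tinyPhantomConfig()
  a <- makePhantom(cfg, seed = 7)
  b <- makePhantom(cfg, seed = 7)
  expect_identical(sampleImage(a), sampleImage(b))
  expect_identical(normalLabel(a), normalLabel(b))
  expect_identical(boundaryLabel(a), boundaryLabel(b))
  c <- makePhantom(cfg, seed = 8)
  expect_false(identical(sampleImage(a), sampleImage(c)))
})

test_that("two tumors of equivalent radius 5-6 give two components of 69-121 px", {
  cfg <- tinyPhantomConfig(nTumorsRange = c(2L, 2L),
                           tumorRadiusRange = c(5, 6))
  for (seed in c(3, 4, 5)) {
    s <- makePhantom(cfg, seed = seed)
    comps <- EBImage::bwlabel(normalLabel(s))
    expect_equal(max(comps), 2)
    sizes <- tabulate(comps[comps > 0])
    expect_true(all(sizes >= 69 & sizes <= 121))
  }
})

test_that("boundaryFromMask matches hand enumeration", {
  m1 <- matrix(0L, 5, 5)
  m1[3, 3] <- 1L
  expect_identical(boundaryFromMask(m1, 1), m1)

  m2 <- matrix(0L, 5, 5)
  m2[2:4, 2:4] <- 1L
  b2 <- boundaryFromMask(m2, 1)
  expected <- m2
  expected[3, 3] <- 0L      # only the center survives a 4-neighborhood erosion
  expect_identical(b2, expected)

  zero <- matrix(0L, 4, 4)
  expect_identical(boundaryFromMask(zero, 1), zero)
  expect_error(boundaryFromMask(matrix(2, 2, 2), 1), "binary")
})

test_that("fillBoundary recovers filled shapes and is idempotent", {
  sq <- matrix(0L, 5, 5)
  sq[2:4, 2:4] <- 1L
  rim <- sq
  rim[3, 3] <- 0L
  expect_identical(fillBoundary(rim), sq)
  expect_identical(fillBoundary(sq), sq)
  zero <- matrix(0L, 4, 4)
  expect_identical(fillBoundary(zero), zero)
})

test_that("filling the boundary label reproduces the normal label", {
  cfg <- tinyPhantomConfig()
  for (seed in 1:6) {
    s <- makePhantom(cfg, seed = seed)
    expect_identical(fillBoundary(boundaryLabel(s)), normalLabel(s))
    expect_true(all(boundaryLabel(s) <= normalLabel(s)))
  }
})

test_that("tumor/background contrast matches the configured offset", {
  cfg <- tinyPhantomConfig(nTumorsRange = c(1L, 1L),
                           tumorRadiusRange = c(10, 14),
                           noiseSigma = 0.01)
  for (seed in 1:4) {
    s <- makePhantom(cfg, seed = seed)
    mask <- normalLabel(s)
    near <- EBImage::dilate(mask, EBImage::makeBrush(13, "diamond"))
    far <- EBImage::dilate(mask, EBImage::makeBrush(7, "diamond"))
    band <- near > 0 & far == 0
    diff <- mean(sampleImage(s)[mask > 0]) - mean(sampleImage(s)[band])
    expect_lt(abs(diff - cfg@tumorContrast), 2 * cfg@noiseSigma)
  }
})

test_that("makeDataset produces subject-encoded ids and the right counts", {
  cfg <- tinyPhantomConfig()
  expect_length(makeDataset(0, 3, cfg, seed = 1), 0)
  ds <- makeDataset(2, 2, cfg, seed = 5)
  expect_length(ds, 4)
  ids <- vapply(ds, sampleID, character(1))
  expect_length(unique(elmseg:::subjectOf(ids)), 2L)
  ds2 <- makeDataset(3, 2, cfg, seed = 5, firstSubject = 4L)
  expect_identical(elmseg:::subjectOf(sampleID(ds2[[1]])), "S0004")
})

test_that("a 215-subject, 3-image dataset has 645 samples", {
  cfg <- phantomConfig(imageSize = 32L, nTumorsRange = c(1L, 1L),
                       tumorRadiusRange = c(3, 6), edgeBlurSigma = 0.5,
                       nDistractorsRange = c(0L, 1L))
  ds <- makeDataset(215, 3, cfg, seed = 1)
  expect_length(ds, 645)
  ids <- vapply(ds, sampleID, character(1))
  expect_length(unique(elmseg:::subjectOf(ids)), 215L)
})

test_that("writeDataset writes PNGs and a manifest", {
  dir <- withr::local_tempdir()
  ds <- makeDataset(1, 2, tinyPhantomConfig(), seed = 1)
  manifest <- writeDataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_identical(nrow(manifest), 2L)
  expect_true(all(file.exists(manifest$image)))
  img <- png::readPNG(manifest$image[1])
  expect_identical(dim(img), c(64L, 64L))
  mask <- png::readPNG(manifest$normal_label[1])
  expect_true(all(mask %in% c(0, 1)))
})
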
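test_that("right-angle rotation follows the counter-clockwise convention", {
  s <- squareSample()
  img <- matrix(0, 3, 3)
  img[1, 1] <- 1           # 0-based (0, 0)
  r <- elmseg:::rot90ccw(img)
  expect_identical(which(r == 1, arr.ind = TRUE)[1, ],
                   c(row = 1L, col = 3L))  # 0-based (0, n-1-0) = (0, 2)

  r90 <- rotateSample(s, 90)
  r360 <- rotateSample(rotateSample(rotateSample(r90, 90), 90), 90)
  expect_identical(sampleImage(r360), sampleImage(s))
  expect_identical(normalLabel(r360), normalLabel(s))

  r180a <- rotateSample(s, 180)
  r180b <- rotateSample(rotateSample(s, 90), 90)
  expect_identical(sampleImage(r180a), sampleImage(r180b))
  expect_identical(sampleClass(r90), sampleClass(s))
  expect_error(rotateSample(s, 45), "90")
})

test_that("outward scaling grows the tumor by the squared zoom factor", {
  s <- squareSample(n = 64L, lo = 28L, hi = 37L)  # 10x10 centered square
  expect_identical(sampleImage(scaleOutward(s, 0)), sampleImage(s))

  z <- scaleOutward(s, 0.5)
  ratio <- sum(normalLabel(z)) / sum(normalLabel(s))
  expect_lt(abs(ratio - 1.5^2), 0.1 * 1.5^2)

  cen <- which(normalLabel(z) > 0, arr.ind = TRUE)
  centroid <- colMeans(cen)
  expect_true(all(abs(centroid - 32.5) <= 2))

  # labels stay consistent after resampling
  expect_identical(fillBoundary(boundaryLabel(z)), normalLabel(z))

  empty <- makePhantom(tinyPhantomConfig(nTumorsRange = c(0L, 0L)), seed = 1)
  expect_error(scaleOutward(empty, 0.5), "tumor-free")
})

test_that("augmentation yields exactly five samples per original", {
  expect_identical(augmentTrainingSet(list()), list())
  s <- squareSample()
  expect_length(augmentTrainingSet(list(s)), 5L)
  aug <- augmentTrainingSet(rep(list(s), 516))
  expect_length(aug, 2580L)
  for (a in augmentTrainingSet(list(s))) {
    expect_identical(fillBoundary(boundaryLabel(a)), normalLabel(a))
  }
})

test_that("subject-level splitting reproduces the 516/129 accounting", {
  ds <- dummyDataset(215, 3)
  sp <- splitDataset(ds, splitPlan(trainFraction = 0.8, seed = 1))
  expect_length(sp$train, 516L)
  expect_length(sp$test, 129L)
  trainSubj <- unique(elmseg:::subjectOf(vapply(sp$train, sampleID, "")))
  testSubj <- unique(elmseg:::subjectOf(vapply(sp$test, sampleID, "")))
  expect_length(intersect(trainSubj, testSubj), 0L)

  sp2 <- splitDataset(ds, splitPlan(trainFraction = 0.8, seed = 1))
  expect_identical(vapply(sp$train, sampleID, ""),
                   vapply(sp2$train, sampleID, ""))
})

test_that("cross-validation folds are subject-disjoint and exhaustive", {
  ds <- dummyDataset(10, 2)
  folds <- splitDataset(ds, splitPlan(foldCount = 5, seed = 2))
  expect_length(folds, 5L)
  testIds <- unlist(lapply(folds, function(f) {
    expect_length(unique(elmseg:::subjectOf(
      vapply(f$test, sampleID, ""))), 2L)
    vapply(f$test, sampleID, "")
  }))
  expect_setequal(testIds, vapply(ds, sampleID, ""))
  expect_identical(anyDuplicated(testIds), 0L)
  expect_error(splitDataset(dummyDataset(3, 1), splitPlan(foldCount = 5)),
               "fewer subjects")
})

test_that("confusion counts match pixel enumeration", {
  pred <- matrix(c(0.9, 0.4, 0.6, 0.1), 2)
  truth <- matrix(c(1, 1, 0, 0), 2)
  cc <- confusionCounts(pred, truth, 0.5)
  expect_equal(c(cc@tp, cc@fn, cc@fp, cc@tn), c(1, 1, 1, 1))

  cc2 <- confusionCounts(truth, truth)
  expect_equal(c(cc2@fp, cc2@fn), c(0, 0))
  cc3 <- confusionCounts(1 - truth, truth)
  expect_equal(c(cc3@tp, cc3@tn), c(0, 0))
  expect_error(confusionCounts(matrix(0.5, 2, 3), truth), "shape")
})

test_that("overlap metrics match their closed forms and sentinels", {
  cc <- new("ConfusionCounts", tp = 8, fp = 2, tn = 0, fn = 2)
  expect_equal(dsc(cc), 0.8)
  expect_equal(precision(new("ConfusionCounts", tp = 9, fp = 1, tn = 0,
                             fn = 0)), 0.9)
  expect_equal(pixelAccuracy(new("ConfusionCounts", tp = 5, tn = 90, fp = 3,
                                 fn = 2)), 0.95)

  perfect <- new("ConfusionCounts", tp = 10, fp = 0, tn = 90, fn = 0)
  expect_identical(c(dsc(perfect), precision(perfect),
                     pixelAccuracy(perfect)), c(1, 1, 1))

  empty <- new("ConfusionCounts", tp = 0, fp = 0, tn = 10, fn = 0)
  expect_identical(c(dsc(empty), precision(empty)), c(1, 1))
  missed <- new("ConfusionCounts", tp = 0, fp = 0, tn = 9, fn = 1)
  expect_identical(precision(missed), 0)
})

test_that("dsc is symmetric in fp/fn and metrics stay in [0,1]", {
  set.seed(1)
  for (i in 1:20) {
    v <- sample(0:50, 4, replace = TRUE)
    cc <- new("ConfusionCounts", tp = v[1], fp = v[2], tn = v[3], fn = v[4])
    sw <- new("ConfusionCounts", tp = v[1], fp = v[4], tn = v[3], fn = v[2])
    expect_equal(dsc(cc), dsc(sw))
    vals <- c(dsc(cc), precision(cc), pixelAccuracy(cc))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("dataset accounting reproduces the augmentation arithmetic", {
  expect_identical(unname(datasetAccounting(215, 3, 0.8, 5)),
                   c(2580, 129, 2709))
  expect_identical(unname(datasetAccounting(215, 3, 0.8, 1)),
                   c(516, 129, 645))
  expect_identical(unname(datasetAccounting(0, 3, 0.8, 5)), c(0, 0, 0))
})
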
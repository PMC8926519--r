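test_that("encoder produces the five-scale pyramid with doubling widths", {
  net <- dualSegNet(networkConfig(baseChannels = 8L), seed = 1)
  img <- matrix(runif(64 * 64), 64)
  feats <- encodeFeatures(net, img)
  sides <- vapply(feats, function(f) dim(f)[1], integer(1))
  widths <- vapply(feats, function(f) dim(f)[3], integer(1))
  expect_identical(sides, c(64L, 32L, 16L, 8L, 4L))
  expect_identical(widths, c(8L, 16L, 32L, 64L, 128L))
  expect_error(encodeFeatures(net, matrix(0, 50, 50)), "divisible")
})

test_that("decoder stages carry the dense upward channel arithmetic", {
  b <- 8L
  dec <- elmseg:::decoderBranchModule(b, 16L * b, useSSE = TRUE,
                                      denseUpward = TRUE)
  dcIn <- vapply(1:4, function(k) {
    dim(dec$children[[paste0("dc", k)]]$children$cbr1$children$conv$params$W$val)[3]
  }, integer(1))
  # stage 1: up(8b) + skip E4(8b); stages 2-4 add the resized deeper
  # encoder feature (E4, E3, E2)
  expect_identical(dcIn, c(16L * b, 16L * b, 8L * b, 4L * b))

  noDense <- elmseg:::decoderBranchModule(b, 16L * b, useSSE = TRUE,
                                          denseUpward = FALSE)
  dcIn0 <- vapply(1:4, function(k) {
    dim(noDense$children[[paste0("dc", k)]]$children$cbr1$children$conv$params$W$val)[3]
  }, integer(1))
  expect_identical(dcIn0, c(16L * b, 8L * b, 4L * b, 2L * b))
})

test_that("full forward pass has the contracted shapes and ranges", {
  net <- dualSegNet(networkConfig(baseChannels = 8L), seed = 2)
  img <- matrix(runif(64 * 64), 64)
  M <- matrix(runif(64 * 64), 64)
  triple <- segmentForward(net, img, M)
  expect_s4_class(triple, "PredictionTriple")
  expect_identical(dim(areaMap(triple)), c(64L, 64L))
  rng <- range(areaMap(triple), edgeMap(triple), detectorMap(triple))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
  expect_true(all(areaMap(triple) > 0 & areaMap(triple) < 1))

  # guidance-free forward is defined
  t0 <- segmentForward(net, img, NULL)
  expect_identical(dim(areaMap(t0)), c(64L, 64L))

  # deterministic in inference mode
  t1 <- segmentForward(net, img, M)
  expect_identical(areaMap(t1), areaMap(triple))
  expect_identical(edgeMap(t1), edgeMap(triple))
})

test_that("the 256-px profile keeps its shape contracts", {
  net <- dualSegNet(networkConfig(baseChannels = 4L), seed = 3)
  img <- matrix(runif(256 * 256), 256)
  feats <- encodeFeatures(net, img)
  expect_identical(dim(feats[[5]])[1:2], c(16L, 16L))
  triple <- segmentForward(net, img, NULL)
  expect_identical(dim(areaMap(triple)), c(256L, 256L))
})

test_that("both decoder branches share shapes but not parameters", {
  net <- dualSegNet(networkConfig(baseChannels = 8L), seed = 4)
  main <- net$children$mainBranch
  edge <- net$children$edgeBranch
  wm <- main$children$dc1$children$cbr1$children$conv$params$W$val
  we <- edge$children$dc1$children$cbr1$children$conv$params$W$val
  expect_identical(dim(wm), dim(we))
  expect_false(identical(wm, we))
})

test_that("mini detector maps a constant raster to a constant interior", {
  net <- dualSegNet(networkConfig(baseChannels = 8L), seed = 5)
  q <- miniUnetDetect(net, matrix(0, 64, 64))
  expect_identical(dim(q), c(64L, 64L))
  expect_true(all(q > 0 & q < 1))
  interior <- q[17:48, 17:48]
  expect_lt(max(interior) - min(interior), 1e-8)
})

test_that("coarse segmenter respects shape and range contracts", {
  unet <- coarseUNet(networkConfig(baseChannels = 8L), seed = 6)
  img <- matrix(runif(64 * 64), 64)
  mask <- coarseSegment(unet, img)
  expect_identical(dim(mask), c(64L, 64L))
  expect_true(all(mask > 0 & mask < 1))
  expect_error(coarseSegment(unet, matrix(0, 40, 40)), "divisible")
})

test_that("class activation map follows the head-weighted sum", {
  f1 <- matrix(c(1, 0, 0, 0), 2, byrow = TRUE)
  f2 <- matrix(c(0, 1, 0, 0), 2, byrow = TRUE)
  raw <- 2 * f1 + 1 * f2
  M <- normalizeLocationMap(raw)
  expect_equal(M, matrix(c(1, 0.5, 0, 0), 2, byrow = TRUE))
  expect_identical(normalizeLocationMap(matrix(3, 4, 4)), matrix(0, 4, 4))

  clf <- camClassifier(networkConfig(baseChannels = 8L), seed = 7)
  img <- matrix(runif(64 * 64), 64)
  res <- classifyAndCam(clf, img, matrix(0, 64, 64))
  expect_equal(sum(res$probs), 1, tolerance = 1e-12)
  expect_true(all(res$locationMap >= 0 & res$locationMap <= 1))
  expect_identical(dim(res$locationMap), c(64L, 64L))
  expect_error(classifyAndCam(clf, img, matrix(0, 32, 32)), "shape")
})

test_that("every parameter of the dual network receives gradient", {
  ag <- asNamespace("elmseg")
  set.seed(31)
  net <- dualSegNet(networkConfig(baseChannels = 4L), seed = 8)
  x <- ag$agConst(array(runif(32 * 32 * 1 * 2), c(32, 32, 1, 2)))
  M <- ag$agConst(array(runif(32 * 32 * 1 * 2), c(32, 32, 1, 2)))
  normal <- array(0, c(32, 32, 1, 2))
  normal[10:20, 10:20, , ] <- 1
  boundary <- array(0, c(32, 32, 1, 2))
  boundary[10:20, c(10, 20), , ] <- 1
  out <- ag$dualSegFwd(net, x, M, train = TRUE)
  area <- ag$agScalarComb(list(
    ag$agBCELoss(out$alpha, normal, 1e-7, FALSE),
    ag$agDiceLoss(out$alpha, normal, 1e-5)))
  edge <- ag$agBCELoss(out$p, boundary, 1e-7, FALSE)
  ed <- ag$agBCELoss(out$q, boundary, 1e-7, FALSE)
  con <- ag$agConLossNode(out$p, out$q, 1e-7)
  total <- ag$agScalarComb(list(area, edge, ed, con), c(1, 1, 1, 0.5))
  params <- ag$moduleParams(net)
  ag$agZeroGrad(params)
  ag$agBackward(total)
  dead <- names(params)[vapply(params, function(p) {
    is.null(p$grad) || all(p$grad == 0)
  }, logical(1))]
  expect_identical(dead, character(0))
})

test_that("ablation configurations build and run forward", {
  img <- matrix(runif(64 * 64), 64)
  for (cfg in list(networkConfig(baseChannels = 4L, useSSE = FALSE),
                   networkConfig(baseChannels = 4L, useBMM = FALSE),
                   networkConfig(baseChannels = 4L, useLocationMap = FALSE),
                   networkConfig(baseChannels = 4L, useEdgeBranch = FALSE),
                   networkConfig(baseChannels = 4L, denseUpward = FALSE))) {
    net <- dualSegNet(cfg, seed = 9)
    triple <- segmentForward(net, img, matrix(0.5, 64, 64))
    expect_identical(dim(areaMap(triple)), c(64L, 64L))
  }
})
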
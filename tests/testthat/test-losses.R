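# Expected values below are frozen from direct arithmetic on the tiny
# rasters (the independent oracle for each loss is its closed form applied
# by hand to 1-4 pixels).

test_that("dice loss matches direct arithmetic", {
  expect_equal(diceLoss(c(1, 1, 0, 0), c(1, 1, 0, 0)), 0, tolerance = 1e-6)
  expect_equal(diceLoss(c(0, 0, 0, 0), c(1, 1, 0, 0)),
               1 - 1e-5 / (2 + 1e-5), tolerance = 1e-9)
  expect_equal(diceLoss(c(0.8, 0.6, 0.2, 0.1), c(1, 1, 0, 0)),
               1 - (2 * 1.4 + 1e-5) / (1.7 + 2 + 1e-5), tolerance = 1e-9)
  expect_lt(abs(diceLoss(c(0.8, 0.6, 0.2, 0.1), c(1, 1, 0, 0)) -
                  0.243243), 1e-6)
  expect_error(diceLoss(c(0.5, 0.5), c(1, 0, 0)), "shape")
})

test_that("rank loss enumerates hard-pixel hinge pairs", {
  # well separated: every pair clears the margin
  expect_equal(rankLoss(c(0.1, 0.1, 0.9, 0.9), c(0, 0, 1, 1), K = 2,
                        mu = 0.3), 0)
  # K=1: hardest background 0.9, hardest tumor 0.4
  expect_equal(rankLoss(c(0.9, 0.1, 0.4, 0.8), c(0, 0, 1, 1), K = 1,
                        mu = 0.3), 0.8, tolerance = 1e-9)
  # K=2: B=(0.9,0.7), T=(0.4,0.6) -> (0.8+0.6+0.6+0.4)/4
  expect_equal(rankLoss(c(0.9, 0.7, 0.4, 0.6), c(0, 0, 1, 1), K = 2,
                        mu = 0.3), 0.6, tolerance = 1e-9)
  # short classes fall back to the actual pair count
  expect_equal(rankLoss(c(0.9, 0.4), c(0, 1), K = 30, mu = 0.3), 0.8,
               tolerance = 1e-9)
  expect_error(rankLoss(c(0.2, 0.3), c(1, 1), K = 2), "background")
})

test_that("rank loss is permutation invariant and monotone in the margin", {
  set.seed(42)
  for (i in 1:10) {
    alpha <- runif(40)
    beta <- rbinom(40, 1, 0.4)
    if (all(beta == 1) || all(beta == 0)) next
    perm <- sample(40)
    expect_equal(rankLoss(alpha, beta, K = 5, mu = 0.3),
                 rankLoss(alpha[perm], beta[perm], K = 5, mu = 0.3),
                 tolerance = 1e-12)
    expect_gte(rankLoss(alpha, beta, K = 5, mu = 0.5),
               rankLoss(alpha, beta, K = 5, mu = 0.2))
  }
})

test_that("localization loss combines Dice and weighted rank terms", {
  cfg <- locLossConfig()
  expect_identical(cfg@lambda1, 0.05)
  expect_identical(cfg@K, 30L)
  expect_identical(cfg@mu, 0.3)
  expect_identical(cfg@smooth, 1e-5)

  expect_equal(locLoss(c(0, 0, 1, 1), c(0, 0, 1, 1)), 0, tolerance = 1e-5)
  alpha <- c(0.8, 0.6, 0.2, 0.1)
  beta <- c(1, 1, 0, 0)
  got <- locLoss(alpha, beta, locLossConfig(K = 2L))
  expect_equal(got, diceLoss(alpha, beta) +
                 0.05 * rankLoss(alpha, beta, K = 2L), tolerance = 1e-12)
  expect_equal(locLoss(alpha, beta, locLossConfig(lambda1 = 0)),
               diceLoss(alpha, beta), tolerance = 1e-12)
})

test_that("area loss is two-sided cross-entropy plus Dice", {
  lab <- c(1, 0)
  got <- areaLoss(c(0.5, 0.5), lab)
  expect_equal(got, 2 * log(2) + 0.5, tolerance = 1e-5)
  expect_lt(abs(got - 1.886292), 1e-6)

  expect_lt(areaLoss(c(1, 0), lab), 1e-4)

  # tiling doubles the pixel-summed cross-entropy term
  bceOnly <- function(a, y) areaLoss(a, y) - diceLoss(a, y)
  expect_equal(bceOnly(rep(c(0.5, 0.5), 2), rep(lab, 2)),
               2 * bceOnly(c(0.5, 0.5), lab), tolerance = 1e-9)

  # the literal positive-class-only form is available behind the flag
  one <- areaLoss(c(0.5, 0.5), lab, segLossConfig(positiveOnly = TRUE))
  expect_equal(one, log(2) + 0.5, tolerance = 1e-5)
})

test_that("edge and detector losses are the clamped pixel-summed BCE", {
  expect_lt(edgeLoss(c(1, 0), c(1, 0)), 1e-5)
  expect_equal(edgeLoss(0.5, 1), log(2), tolerance = 1e-9)
  expect_equal(edLoss(0.5, 1), edgeLoss(0.5, 1), tolerance = 1e-15)
  q <- runif(16)
  y <- rbinom(16, 1, 0.5)
  expect_equal(edLoss(q, y), edgeLoss(q, y), tolerance = 1e-15)
  expect_error(edgeLoss(c(0.5, 0.5), c(1)), "shape")
})

test_that("consistency loss matches its closed form and is symmetric", {
  expect_equal(conLoss(0.8, 0.8), 0)
  expect_equal(conLoss(0.8, 0.5), 0.3 * log(1.6), tolerance = 1e-9)
  expect_lt(abs(conLoss(0.8, 0.5) - 0.141003), 2e-6)
  expect_equal(conLoss(0.8, 0.5), conLoss(0.5, 0.8), tolerance = 1e-15)

  # closed form Sum (p-q) log(p/q) vs the printed two-sum definition
  set.seed(7)
  for (i in 1:100) {
    p <- runif(25, 0.01, 0.99)
    q <- runif(25, 0.01, 0.99)
    twoSum <- -sum(p * log(q / p)) - sum(q * log(p / q))
    got <- conLoss(p, q)
    expect_lt(abs(got - twoSum) / abs(twoSum), 1e-10)
    expect_gte(got, 0)
  }
})

test_that("segmentation loss sums its four terms with lambda2", {
  cfg <- segLossConfig()
  expect_identical(cfg@lambda2, 0.5)

  preds <- list(alpha = c(0.5, 0.5), p = 0.5, q = 0.5)
  # built so the per-term oracles above apply: area on a 2-pixel raster,
  # edge/ed on a 1-pixel boundary, con between two equal maps
  sample <- list(normal = c(1, 0), boundary = 1)
  preds1 <- list(alpha = c(0.5, 0.5), p = c(0.5), q = c(0.5))
  out <- segLoss(preds1, sample)
  expect_lt(abs(out$area - 1.886292), 1e-6)
  expect_lt(abs(out$edge - 0.693147), 1e-6)
  expect_lt(abs(out$ed - 0.693147), 1e-6)
  expect_equal(out$con, 0, tolerance = 1e-12)
  expect_equal(out$total,
               out$area + out$edge + out$ed + 0.5 * out$con,
               tolerance = 1e-12)

  # frozen sum of the independent per-term oracles
  out2 <- segLoss(list(alpha = c(0.5, 0.5), p = c(0.8), q = c(0.5)),
                  sample)
  expect_lt(abs(out2$con - 0.141003), 2e-6)
  expect_equal(out2$total, 1.886292 + 0.693147 + edgeLoss(0.8, 1) +
                 0.5 * 0.1410011, tolerance = 1e-5)

  # lambda2 = 0 removes the consistency term
  out3 <- segLoss(list(alpha = c(0.5, 0.5), p = c(0.8), q = c(0.5)),
                  sample, segLossConfig(lambda2 = 0))
  expect_equal(out3$total, out2$total - 0.5 * out2$con, tolerance = 1e-9)

  # perfect predictions give a near-zero total
  s <- squareSample()
  perfect <- predictionTriple(normalLabel(s) + 0, boundaryLabel(s) + 0,
                              boundaryLabel(s) + 0)
  expect_lt(segLoss(perfect, s)$total, 1e-3)
})

test_that("dice loss agrees with the Dice metric for binary predictions", {
  set.seed(3)
  for (i in 1:10) {
    alpha <- rbinom(64, 1, 0.3)
    beta <- rbinom(64, 1, 0.3)
    cc <- confusionCounts(matrix(alpha, 8), matrix(beta, 8), 0.5)
    expect_equal(diceLoss(alpha, beta), 1 - dsc(cc), tolerance = 1e-4)
  }
})

test_that("losses stay finite on clamped extreme inputs", {
  cfg <- segLossConfig()
  vals <- c(areaLoss(c(0, 1), c(1, 0), cfg),
            edgeLoss(c(0, 1), c(1, 0), cfg),
            conLoss(c(0, 1), c(1, 0), cfg),
            diceLoss(c(0, 0), c(0, 0)))
  expect_true(all(is.finite(vals)))
})
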
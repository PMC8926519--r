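# independent oracle: plain nested-loop depth-wise sliding-window sum with
# zero padding
dwOracle <- function(f, k) {
  h <- dim(f)[1]; w <- dim(f)[2]; cc <- dim(f)[3]; n <- dim(f)[4]
  s <- dim(k)[1]
  pad <- (s - 1) / 2
  y <- array(0, dim(f))
  for (b in seq_len(n)) for (ch in seq_len(cc)) {
    for (i in seq_len(h)) for (j in seq_len(w)) {
      acc <- 0
      for (ki in seq_len(s)) for (kj in seq_len(s)) {
        ii <- i + ki - 1 - pad
        jj <- j + kj - 1 - pad
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
          acc <- acc + f[ii, jj, ch, b] * k[ki, kj, ch, b]
        }
      }
      y[i, j, ch, b] <- acc
    }
  }
  y
}

test_that("dynamic depth-wise convolution matches the brute-force oracle", {
  set.seed(11)
  for (s in c(1L, 3L, 5L)) {
    f <- array(rnorm(7 * 7 * 2 * 2), c(7, 7, 2, 2))
    k <- array(rnorm(s * s * 2 * 2), c(s, s, 2, 2))
    got <- elmseg:::dwconv_fwd_cpp(f, k)
    want <- dwOracle(f, k)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-6)
  }
})

test_that("double-convolution block preserves space, sets channels, rectifies", {
  set.seed(1)
  blk <- doubleConvBlock(8L, 16L)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  y <- blockForward(blk, x, train = TRUE)
  expect_identical(dim(y), c(16L, 16L, 16L, 1L))
  expect_true(all(y >= 0))
})

test_that("spatial gate halves a zero-projection input and contracts", {
  set.seed(2)
  blk <- sseBlock(4L)
  blk$children$proj$params$W$val[] <- 0
  blk$children$proj$params$b$val[] <- 0
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  y <- blockForward(blk, x)
  expect_equal(y, x / 2, tolerance = 1e-12)

  blk2 <- sseBlock(4L)
  y2 <- blockForward(blk2, x)
  expect_true(all(abs(y2) <= abs(x) + 1e-12))
  expect_identical(dim(y2), dim(x))

  # single channel, unit projection: gate is 0.5 wherever the input is 0
  blk3 <- sseBlock(1L)
  blk3$children$proj$params$W$val[] <- 1
  blk3$children$proj$params$b$val[] <- 0
  x3 <- array(0, c(4, 4, 1, 1))
  expect_true(all(blockForward(blk3, x3) == 0))
})

test_that("adaptive convolutional block has the contracted shape and kernels", {
  set.seed(3)
  expect_error(acbBlock(8L, 4L, 2L), "odd")
  expect_error(acbBlock(8L, 8L, 3L), "cPrime")

  x <- array(rnorm(16 * 16 * 64), c(16, 16, 64, 1))
  blk <- acbBlock(64L, 32L, 3L)
  y <- blockForward(blk, x)
  expect_identical(dim(y), c(16L, 16L, 32L, 1L))

  # s = 1 with the kernel generator forced to all-ones reduces to F(x)
  blk1 <- acbBlock(8L, 4L, 1L)
  blk1$children$kconv$params$W$val[] <- 0
  blk1$children$kconv$params$b$val[] <- 1
  x8 <- array(rnorm(6 * 6 * 8), c(6, 6, 8, 1))
  Fx <- elmseg:::convFwd(blk1$children$fconv, elmseg:::agConst(x8))$val
  expect_equal(blockForward(blk1, x8), Fx, tolerance = 1e-12)
})

test_that("dynamic kernels are per-sample (batch equivariance)", {
  set.seed(4)
  blk <- acbBlock(6L, 3L, 3L)
  x <- array(rnorm(8 * 8 * 6 * 3), c(8, 8, 6, 3))
  y <- blockForward(blk, x)
  perm <- c(3L, 1L, 2L)
  yp <- blockForward(blk, x[, , , perm, drop = FALSE])
  expect_equal(yp, y[, , , perm, drop = FALSE], tolerance = 1e-12)
})

test_that("bottleneck multiscale module channel arithmetic and fusion", {
  set.seed(5)
  blk <- bmmBlock(64L, bmmConfig(outChannels = 64L))
  expect_identical(blk$concatChannels, 3L * 32L + 64L + 1L)  # 161

  x <- array(rnorm(16 * 16 * 64), c(16, 16, 64, 1))
  M <- matrix(runif(16 * 16), 16)
  y <- blockForward(blk, x, M = M)
  expect_identical(dim(y), c(16L, 16L, 64L, 1L))

  # zero projection weights on the map channel make the output map-free
  blk$children$proj$params$W$val[, , 161, ] <- 0
  y0 <- blockForward(blk, x, M = matrix(0, 16, 16))
  y1 <- blockForward(blk, x, M = matrix(1, 16, 16))
  expect_equal(y0, y1, tolerance = 1e-12)

  # a coarser map is resampled to the feature scale before aggregation
  y2 <- blockForward(blk, x, M = matrix(0.5, 4, 4))
  expect_identical(dim(y2), dim(y))

  # single kernel size with identity projection reduces to the composed ops
  cfg1 <- bmmConfig(kernelSizes = 1L, reducedChannels = 3L,
                    outChannels = 10L)
  blk1 <- bmmBlock(6L, cfg1)
  expect_identical(blk1$concatChannels, 3L + 6L + 1L)
  acbOut <- blockForward(blk1$children$acb1,
                         x6 <- array(rnorm(8 * 8 * 6), c(8, 8, 6, 1)))
  got <- blockForward(blk1, x6, M = matrix(0.5, 8, 8))
  manual <- elmseg:::agConcat(list(
    elmseg:::agConst(acbOut), elmseg:::agConst(x6),
    elmseg:::agConst(array(0.5, c(8, 8, 1, 1)))))
  want <- elmseg:::convFwd(blk1$children$proj, manual)$val
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("blocks preserve spatial dimensions", {
  set.seed(6)
  x <- array(rnorm(12 * 12 * 8), c(12, 12, 8, 2))
  expect_identical(dim(blockForward(doubleConvBlock(8L, 4L), x))[1:2],
                   c(12L, 12L))
  expect_identical(dim(blockForward(sseBlock(8L), x))[1:2], c(12L, 12L))
  expect_identical(dim(blockForward(acbBlock(8L, 4L, 5L), x))[1:2],
                   c(12L, 12L))
})
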
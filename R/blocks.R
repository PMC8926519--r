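# Reusable network components: double-convolution block, spatial
# squeeze-and-excitation gate, adaptive convolutional block (dynamic
# depth-wise kernels) and the bottleneck multiscale module that fuses the
# multi-kernel features with the encoder output and the location map.

convLayer <- function(cin, cout, k = 3L) {
  m <- newModule("conv")
  fanIn <- k * k * cin
  m$params$W <- agParam(array(stats::rnorm(k * k * cin * cout,
                                           sd = sqrt(2 / fanIn)),
                              c(k, k, cin, cout)))
  m$params$b <- agParam(rep(0, cout))
  m
}

convFwd <- function(m, x) agConv2d(x, m$params$W, m$params$b)

bnLayer <- function(c) {
  m <- newModule("bn")
  m$params$gamma <- agParam(rep(1, c))
  m$params$beta <- agParam(rep(0, c))
  m$buffers$runMean <- rep(0, c)
  m$buffers$runVar <- rep(1, c)
  m
}

bnFwd <- function(m, x, train) {
  agBatchNorm(x, m$params$gamma, m$params$beta, m, train)
}

convBNRelu <- function(cin, cout, k = 3L) {
  m <- newModule("cbr")
  m$children$conv <- convLayer(cin, cout, k)
  m$children$bn <- bnLayer(cout)
  m
}

cbrFwd <- function(m, x, train) {
  agRelu(bnFwd(m$children$bn, convFwd(m$children$conv, x), train))
}

coerceFeature <- function(x) {
  if (isNode(x)) return(x)
  d <- dim(x)
  if (is.null(d)) stop("feature input must be an array")
  if (length(d) == 2L) x <- array(x, c(d, 1L, 1L))
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  agConst(x)
}

featureOut <- function(node, wasNode) if (wasNode) node else node$val

#' Double-convolution block
#'
#' Two 3x3 convolution + batch normalization + rectifier stages; spatial
#' size is preserved (same padding) and the channel count becomes
#' `outChannels`.
#'
#' @param inChannels,outChannels channel counts
#' @return a block object usable with [blockForward()]
#' @export
doubleConvBlock <- function(inChannels, outChannels) {
  m <- newModule("doubleConv")
  m$children$cbr1 <- convBNRelu(inChannels, outChannels)
  m$children$cbr2 <- convBNRelu(outChannels, outChannels)
  m$forwardFun <- function(self, x, train) {
    cbrFwd(self$children$cbr2, cbrFwd(self$children$cbr1, x, train), train)
  }
  m
}

#' Spatial squeeze-and-excitation gate
#'
#' A 1x1 projection squeezes the channels to a single plane, a logistic
#' activation maps it into (0,1), and every input channel is rescaled by
#' this spatial gate. Shape is preserved; output magnitudes never exceed
#' the input's.
#'
#' @param inChannels channel count of the gated feature
#' @return a block object usable with [blockForward()]
#' @export
sseBlock <- function(inChannels) {
  m <- newModule("sse")
  m$children$proj <- convLayer(inChannels, 1L, k = 1L)
  m$forwardFun <- function(self, x, train) {
    gate <- agSigmoid(convFwd(self$children$proj, x))
    agMulGate(x, gate)
  }
  m
}

#' Adaptive convolutional block (dynamic depth-wise kernels)
#'
#' `F(x)` is a 1x1 convolution of the input to `cPrime` channels. The
#' kernel generator adaptively max-pools the input to `s x s`, then adjusts
#' channels to `cPrime` with a 1x1 convolution; the result is used as a
#' per-sample depth-wise convolution kernel applied to `F(x)` with zero
#' "same" padding, so the output stays `h x w x cPrime`.
#'
#' @param inChannels input channel count
#' @param cPrime reduced channel count (must be < `inChannels`)
#' @param s odd kernel size
#' @return a block object usable with [blockForward()]
#' @export
acbBlock <- function(inChannels, cPrime, s) {
  if (s %% 2L == 0L) stop("kernel size s must be odd")
  if (cPrime >= inChannels) stop("cPrime must be < inChannels")
  m <- newModule("acb")
  m$s <- as.integer(s)
  m$children$fconv <- convLayer(inChannels, cPrime, k = 1L)
  m$children$kconv <- convLayer(inChannels, cPrime, k = 1L)
  m$forwardFun <- function(self, x, train) {
    Fx <- convFwd(self$children$fconv, x)
    pooled <- agAdaMaxPool(x, self$s)
    Ks <- convFwd(self$children$kconv, pooled)
    agDwConv(Fx, Ks)
  }
  m
}

#' Bottleneck multiscale module
#'
#' Runs one adaptive convolutional block per kernel size, concatenates
#' their outputs `y'`, then aggregates `[y', x, M]` (the original feature
#' map and the location map, resampled to the feature scale) and adjusts
#' channels with a 1x1 convolution. With kernel sizes 1/3/5 and
#' `cPrime = c/2` the pre-projection concatenation carries
#' `3c' + c + 1` channels.
#'
#' @param inChannels encoder output channels `c`
#' @param config a [BMMConfig-class]; `NA` `reducedChannels` means `c/2`,
#'   `NA` `outChannels` means `c`
#' @param withMap include the location-map channel in the aggregation
#' @return a block object; its forward takes `(x, M)`
#' @export
bmmBlock <- function(inChannels, config = bmmConfig(), withMap = TRUE) {
  validObject(config)
  cPrime <- if (is.na(config@reducedChannels)) {
    as.integer(inChannels / 2)
  } else config@reducedChannels
  if (cPrime >= inChannels) stop("reducedChannels must be < inChannels")
  outC <- if (is.na(config@outChannels)) inChannels else config@outChannels
  m <- newModule("bmm")
  m$kernelSizes <- config@kernelSizes
  m$withMap <- withMap
  for (s in config@kernelSizes) {
    m$children[[paste0("acb", s)]] <- acbBlock(inChannels, cPrime, s)
  }
  concatC <- length(config@kernelSizes) * cPrime + inChannels +
    as.integer(withMap)
  m$concatChannels <- concatC
  m$children$proj <- convLayer(concatC, outC, k = 1L)
  m$forwardFun <- function(self, x, M, train) {
    ys <- lapply(self$kernelSizes, function(s) {
      blk <- self$children[[paste0("acb", s)]]
      blk$forwardFun(blk, x, train)
    })
    parts <- c(ys, list(x))
    if (self$withMap) {
      d <- dim(x$val)
      Mn <- agResize(M, d[1], d[2])
      if (dim(Mn$val)[3] != 1L) stop("location map must be single-channel")
      parts <- c(parts, list(Mn))
    }
    convFwd(self$children$proj, agConcat(parts))
  }
  m
}

#' Apply a network block to a feature map
#'
#' Feature maps are `(h, w, c, n)` arrays (matrices and 3D arrays are
#' promoted); plain arrays in give plain arrays out, autodiff nodes give
#' nodes.
#'
#' @param block a block from [doubleConvBlock()], [sseBlock()],
#'   [acbBlock()] or [bmmBlock()]
#' @param x input feature map
#' @param M location map (for [bmmBlock()] only)
#' @param train batch-normalization mode
#' @return the output feature map
#' @export
blockForward <- function(block, x, M = NULL, train = FALSE) {
  wasNode <- isNode(x)
  xn <- coerceFeature(x)
  out <- if (identical(block$type, "bmm")) {
    if (is.null(M)) stop("bmm block requires a location map M")
    block$forwardFun(block, xn, coerceFeature(M), train)
  } else {
    block$forwardFun(block, xn, train)
  }
  featureOut(out, wasNode)
}
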
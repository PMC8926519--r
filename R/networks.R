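# The two networks: the localization network (coarse U-Net segmenter +
# separable-convolution classifier + class activation mapping) and the
# dual-branch segmentation network (shared 5-stage encoder, main and edge
# decoders with dense upward connections, and a small boundary detector
# appended to the main branch).

checkImageSide <- function(side) {
  if (side %% 16L != 0L) {
    stop("image side must be divisible by 16 (got ", side, ")")
  }
  invisible(TRUE)
}

asImageBatch <- function(x) {
  if (isNode(x)) return(x)
  d <- dim(x)
  if (length(d) == 2L) x <- array(x, c(d, 1L, 1L))
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  agConst(x)
}

upsampleLayer <- function(cin, cout) {
  m <- newModule("up")
  m$children$conv <- convLayer(cin, cout, k = 3L)
  m$children$bn <- bnLayer(cout)
  m
}

upFwd <- function(m, x, train) {
  d <- dim(x$val)
  agRelu(bnFwd(m$children$bn,
               convFwd(m$children$conv, agResize(x, 2L * d[1], 2L * d[2])),
               train))
}

## ---- encoder ----------------------------------------------------------

encoderModule <- function(base, useSSE = TRUE) {
  m <- newModule("encoder")
  widths <- base * c(1L, 2L, 4L, 8L, 16L)
  m$widths <- widths
  m$useSSE <- useSSE
  m$children$dc1 <- doubleConvBlock(1L, widths[1])
  for (k in 2:5) {
    m$children[[paste0("dc", k)]] <-
      doubleConvBlock(widths[k - 1], widths[k])
    if (useSSE) {
      m$children[[paste0("sse", k)]] <- sseBlock(widths[k])
    }
  }
  m
}

encoderFwd <- function(m, x, train) {
  feats <- vector("list", 5L)
  dc1 <- m$children$dc1
  feats[[1]] <- dc1$forwardFun(dc1, x, train)
  for (k in 2:5) {
    h <- agMaxPool2(feats[[k - 1]])
    dck <- m$children[[paste0("dc", k)]]
    h <- dck$forwardFun(dck, h, train)
    if (m$useSSE) {
      ssek <- m$children[[paste0("sse", k)]]
      h <- ssek$forwardFun(ssek, h, train)
    }
    feats[[k]] <- h
  }
  feats
}

## ---- decoder branch ---------------------------------------------------

# stage 1 is deepest; stage k upsamples x2, gates, concatenates the
# same-scale encoder skip plus (stages 2-4) a deeper encoder feature
# resized to the stage's scale (the dense upward connection), then applies
# a double convolution; a final 1x1 convolution + logistic yields the
# probability raster
decoderBranchModule <- function(base, bottleneckC, useSSE = TRUE,
                                denseUpward = TRUE) {
  m <- newModule("decoder")
  outC <- base * c(8L, 4L, 2L, 1L)
  skipC <- base * c(8L, 4L, 2L, 1L)    # E4, E3, E2, E1
  denseC <- c(0L, base * 8L, base * 4L, base * 2L)  # -, E4, E3, E2
  if (!denseUpward) denseC[] <- 0L
  m$outC <- outC
  m$useSSE <- useSSE
  m$denseUpward <- denseUpward
  inC <- c(bottleneckC, outC[1:3])
  for (k in 1:4) {
    m$children[[paste0("up", k)]] <- upsampleLayer(inC[k], outC[k])
    if (useSSE) m$children[[paste0("sse", k)]] <- sseBlock(outC[k])
    m$children[[paste0("dc", k)]] <-
      doubleConvBlock(outC[k] + skipC[k] + denseC[k], outC[k])
  }
  m$children$head <- convLayer(outC[4], 1L, k = 1L)
  # start near the foreground prior so early epochs are not dominated by
  # the background class of the pixel-summed cross-entropy
  m$children$head$params$b$val <- -2
  m
}

decoderBranchFwd <- function(m, bottleneck, encFeats, train) {
  if (length(encFeats) < 4L) {
    stop("decoder branch needs encoder features E1..E4")
  }
  skips <- list(encFeats[[4]], encFeats[[3]], encFeats[[2]], encFeats[[1]])
  dense <- list(NULL, encFeats[[4]], encFeats[[3]], encFeats[[2]])
  h <- bottleneck
  for (k in 1:4) {
    upk <- m$children[[paste0("up", k)]]
    h <- upFwd(upk, h, train)
    if (m$useSSE) {
      ssek <- m$children[[paste0("sse", k)]]
      h <- ssek$forwardFun(ssek, h, train)
    }
    parts <- list(h, skips[[k]])
    if (m$denseUpward && !is.null(dense[[k]])) {
      d <- dim(h$val)
      parts <- c(parts, list(agResize(dense[[k]], d[1], d[2])))
    }
    dck <- m$children[[paste0("dc", k)]]
    h <- dck$forwardFun(dck, agConcat(parts), train)
  }
  agSigmoid(convFwd(m$children$head, h))
}

## ---- Mini-UNet boundary detector --------------------------------------

miniUnetModule <- function(depth = 2L, base = 8L) {
  m <- newModule("miniUnet")
  m$depth <- as.integer(depth)
  widths <- base * 2L^(seq_len(depth) - 1L)
  m$children$enc1 <- doubleConvBlock(1L, widths[1])
  for (l in seq_len(depth - 1L)) {
    m$children[[paste0("enc", l + 1L)]] <-
      doubleConvBlock(widths[l], widths[l + 1L])
    m$children[[paste0("up", l)]] <-
      upsampleLayer(widths[l + 1L], widths[l])
    m$children[[paste0("dec", l)]] <-
      doubleConvBlock(2L * widths[l], widths[l])
  }
  m$children$head <- convLayer(widths[1], 1L, k = 1L)
  m$children$head$params$b$val <- -2
  m
}

miniUnetFwd <- function(m, x, train) {
  depth <- m$depth
  feats <- vector("list", depth)
  e1 <- m$children$enc1
  feats[[1]] <- e1$forwardFun(e1, x, train)
  for (l in seq_len(depth - 1L)) {
    el <- m$children[[paste0("enc", l + 1L)]]
    feats[[l + 1L]] <- el$forwardFun(el, agMaxPool2(feats[[l]]), train)
  }
  h <- feats[[depth]]
  for (l in rev(seq_len(depth - 1L))) {
    h <- upFwd(m$children[[paste0("up", l)]], h, train)
    dl <- m$children[[paste0("dec", l)]]
    h <- dl$forwardFun(dl, agConcat(list(h, feats[[l]])), train)
  }
  agSigmoid(convFwd(m$children$head, h))
}

## ---- dual-branch segmentation network ---------------------------------

#' Construct the dual-branch segmentation network
#'
#' A five-stage encoder (double convolutions, four max poolings, spatial
#' gates after each pooling) feeds the dynamic-kernel bottleneck multiscale
#' module, which also aggregates the location map. Two structurally
#' identical decoders with independent parameters — the main (area) branch
#' and the edge branch — recover full resolution through four
#' upsample/gate/concatenate/double-convolution stages with dense upward
#' connections; a small boundary-detector network extracts the rim of the
#' main branch's prediction.
#'
#' @param config a [NetworkConfig-class]; ablation flags remove the spatial
#'   gates, the multiscale bottleneck, the location-map input, the edge
#'   branch or the dense connections
#' @param seed parameter-initialization seed
#' @return a network object for [segmentForward()]
#' @export
dualSegNet <- function(config = networkConfig(), seed = 1L) {
  validObject(config)
  withSeed(seed, {
    b <- config@baseChannels
    net <- newModule("dualSegNet")
    net$config <- config
    net$children$encoder <- encoderModule(b, config@useSSE)
    encOut <- 16L * b
    if (config@useBMM) {
      net$children$bmm <- bmmBlock(
        encOut,
        bmmConfig(kernelSizes = config@kernelSizes,
                  outChannels = encOut),
        withMap = config@useLocationMap)
    } else {
      inC <- encOut + as.integer(config@useLocationMap)
      net$children$bottleneckProj <- convLayer(inC, encOut, k = 1L)
    }
    net$children$mainBranch <- decoderBranchModule(
      b, encOut, config@useSSE, config@denseUpward)
    if (config@useEdgeBranch) {
      net$children$edgeBranch <- decoderBranchModule(
        b, encOut, config@useSSE, config@denseUpward)
    }
    net$children$miniUnet <- miniUnetModule(config@miniUnetDepth)
    net
  })
}

dualSegFwd <- function(net, x, M, train) {
  config <- net$config
  feats <- encoderFwd(net$children$encoder, x, train)
  e5 <- feats[[5]]
  if (config@useBMM) {
    bmm <- net$children$bmm
    bott <- bmm$forwardFun(bmm, e5, M, train)
  } else {
    parts <- list(e5)
    if (config@useLocationMap) {
      d <- dim(e5$val)
      parts <- c(parts, list(agResize(M, d[1], d[2])))
    }
    bott <- convFwd(net$children$bottleneckProj,
                    if (length(parts) > 1L) agConcat(parts) else parts[[1]])
  }
  alpha <- decoderBranchFwd(net$children$mainBranch, bott, feats, train)
  p <- if (config@useEdgeBranch) {
    decoderBranchFwd(net$children$edgeBranch, bott, feats, train)
  } else NULL
  q <- miniUnetFwd(net$children$miniUnet, alpha, train)
  list(alpha = alpha, p = p, q = q)
}

#' Run the dual-branch network on one image
#'
#' @param net a network from [dualSegNet()]
#' @param image grayscale matrix with side divisible by 16, values in \[0,1\]
#' @param M location map in \[0,1\] (matrix at any scale; resampled
#'   internally). `NULL` means guidance-free (all-zero map).
#' @param train batch-normalization mode
#' @return a [PredictionTriple-class]; with the edge branch ablated, `p`
#'   is the detector output `q`
#' @export
segmentForward <- function(net, image, M = NULL, train = FALSE) {
  checkImageSide(nrow(image))
  if (is.null(M)) M <- matrix(0, nrow(image), ncol(image))
  out <- agNoGrad(dualSegFwd(net, asImageBatch(image), asImageBatch(M),
                             train))
  alpha <- matrix(out$alpha$val, nrow(image))
  q <- matrix(out$q$val, nrow(image))
  p <- if (is.null(out$p)) q else matrix(out$p$val, nrow(image))
  predictionTriple(alpha, p, q)
}

#' Encoder features for one image
#'
#' @param net a [dualSegNet()] network
#' @param image grayscale matrix, side divisible by 16
#' @return list of five `(h, w, c, 1)` arrays at scales 1, 1/2, ..., 1/16
#' @export
encodeFeatures <- function(net, image) {
  checkImageSide(nrow(image))
  feats <- agNoGrad(encoderFwd(net$children$encoder, asImageBatch(image),
                               train = FALSE))
  lapply(feats, function(f) f$val)
}

#' Boundary detector on an area prediction
#'
#' @param net a [dualSegNet()] network
#' @param areaPred single-channel probability matrix in \[0,1\]
#' @return boundary probability matrix of the same size
#' @export
miniUnetDetect <- function(net, areaPred) {
  out <- agNoGrad(miniUnetFwd(net$children$miniUnet,
                              asImageBatch(areaPred), train = FALSE))
  matrix(out$val, nrow(areaPred))
}

## ---- coarse segmenter (classic U-Net) ---------------------------------

#' Construct the coarse localization U-Net
#'
#' A classic U-Net with the same encoder/decoder widths as the dual-branch
#' network but a single decoder, plain same-scale skips and no gates; the
#' head is a 1x1 convolution with a logistic activation.
#'
#' @param config a [NetworkConfig-class] (only `baseChannels` is used)
#' @param seed parameter-initialization seed
#' @return a network object for [coarseSegment()]
#' @export
coarseUNet <- function(config = networkConfig(), seed = 1L) {
  validObject(config)
  withSeed(seed, {
    b <- config@baseChannels
    net <- newModule("coarseUNet")
    net$config <- config
    net$children$encoder <- encoderModule(b, useSSE = FALSE)
    net$children$decoder <- decoderBranchModule(b, 16L * b, useSSE = FALSE,
                                                denseUpward = FALSE)
    net
  })
}

coarseFwd <- function(net, x, train) {
  feats <- encoderFwd(net$children$encoder, x, train)
  decoderBranchFwd(net$children$decoder, feats[[5]], feats, train)
}

#' Coarse tumor-probability mask from the localization U-Net
#'
#' @param net a [coarseUNet()] network
#' @param image grayscale matrix, side divisible by 16
#' @return probability matrix in \[0,1\]
#' @export
coarseSegment <- function(net, image) {
  checkImageSide(nrow(image))
  out <- agNoGrad(coarseFwd(net, asImageBatch(image), train = FALSE))
  matrix(out$val, nrow(image))
}

## ---- classifier + class activation mapping ----------------------------

sepConvLayer <- function(cin, cout, k = 3L) {
  m <- newModule("sepconv")
  m$params$Wd <- agParam(array(stats::rnorm(k * k * cin,
                                            sd = sqrt(2 / (k * k))),
                               c(k, k, cin)))
  m$children$pw <- convLayer(cin, cout, k = 1L)
  m
}

sepConvFwd <- function(m, x) {
  convFwd(m$children$pw, agDwConvStatic(x, m$params$Wd))
}

#' Construct the compact separable-convolution classifier
#'
#' Entry 3x3 convolution, two downsampling separable-convolution blocks
#' and a final separable convolution provide the feature maps; global
#' average pooling and a linear head give the two-class logits. The class
#' activation map is the head-weighted sum of the final convolutional
#' features.
#'
#' @param config a [NetworkConfig-class]
#' @param seed parameter-initialization seed
#' @return a classifier object for [classifyAndCam()]
#' @export
camClassifier <- function(config = networkConfig(), seed = 1L) {
  withSeed(seed, {
    b <- max(8L, config@baseChannels)
    net <- newModule("camClassifier")
    net$widths <- c(b, 2L * b, 4L * b, 4L * b)
    net$children$entry <- convBNRelu(2L, b)
    net$children$sep1 <- sepConvLayer(b, 2L * b)
    net$children$bn1 <- bnLayer(2L * b)
    net$children$sep2 <- sepConvLayer(2L * b, 4L * b)
    net$children$bn2 <- bnLayer(4L * b)
    net$children$sep3 <- sepConvLayer(4L * b, 4L * b)
    net$children$bn3 <- bnLayer(4L * b)
    net$children$sep4 <- sepConvLayer(4L * b, 4L * b)
    net$children$bn4 <- bnLayer(4L * b)
    net$params$headW <- agParam(matrix(stats::rnorm(2L * 4L * b,
                                                    sd = sqrt(1 / (4 * b))),
                                       2L, 4L * b))
    net$params$headB <- agParam(rep(0, 2L))
    net
  })
}

classifierFwd <- function(net, x, train) {
  h <- cbrFwd(net$children$entry, x, train)
  h <- agMaxPool2(agRelu(bnFwd(net$children$bn1,
                               sepConvFwd(net$children$sep1, h), train)))
  h <- agMaxPool2(agRelu(bnFwd(net$children$bn2,
                               sepConvFwd(net$children$sep2, h), train)))
  h <- agMaxPool2(agRelu(bnFwd(net$children$bn3,
                               sepConvFwd(net$children$sep3, h), train)))
  feats <- agRelu(bnFwd(net$children$bn4,
                        sepConvFwd(net$children$sep4, h), train))
  logits <- agLinear(agGAP(feats), net$params$headW, net$params$headB)
  list(logits = logits, feats = feats)
}

# class index convention: 1 = absent, 2 = present
classIndex <- function(labels) ifelse(labels == "present", 2L, 1L)

#' Normalize a raw activation map to \[0,1\]
#'
#' Min-max normalization; degenerate constant maps become all-zeros.
#'
#' @param m numeric matrix
#' @return matrix in \[0,1\]
#' @export
normalizeLocationMap <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Class probabilities and class activation map for one image
#'
#' The image and its coarse mask are stacked into a 2-channel input; the
#' classifier's final convolutional features `f_k`, global average pooling
#' and the linear head give the softmax class probabilities. The location
#' map is the tumor-present class activation `M(u,v) = sum_k w_k f_k(u,v)`,
#' min-max normalized to \[0,1\] and bilinearly upsampled to the image size.
#'
#' @param net a [camClassifier()] network
#' @param image grayscale matrix
#' @param coarseMask probability matrix of the same shape
#' @return list with `probs` (named: absent, present) and `locationMap`
#' @export
classifyAndCam <- function(net, image, coarseMask) {
  if (!identical(dim(image), dim(coarseMask))) {
    stop("image and coarseMask must share a shape")
  }
  d <- dim(image)
  x <- array(0, c(d[1], d[2], 2L, 1L))
  x[, , 1L, 1L] <- image
  x[, , 2L, 1L] <- coarseMask
  out <- agNoGrad(classifierFwd(net, agConst(x), train = FALSE))
  probs <- softmaxProbs(out$logits$val)[, 1L]
  names(probs) <- c("absent", "present")
  fv <- out$feats$val                      # (h', w', c, 1)
  w <- net$params$headW$val[2L, ]          # tumor-present head weights
  fd <- dim(fv)
  fm <- matrix(fv, fd[1] * fd[2], fd[3])
  raw <- matrix(fm %*% w, fd[1], fd[2])
  M <- normalizeLocationMap(raw)
  M <- bilinearResizeMat(M, d[1])
  M <- pmin(pmax(M, 0), 1)
  list(probs = probs, locationMap = M)
}

## ---- batched inference helpers ----------------------------------------

chunkSeq <- function(n, size) {
  if (n == 0L) return(list())
  unname(split(seq_len(n), ceiling(seq_len(n) / size)))
}

# batched eval-mode forward passes (inference over many images)
segmentForwardMany <- function(net, images, maps, batchSize = 8L) {
  out <- vector("list", length(images))
  if (!length(images)) return(out)
  d <- dim(images[[1]])
  for (idx in chunkSeq(length(images), batchSize)) {
    x <- array(0, c(d[1], d[2], 1L, length(idx)))
    M <- array(0, c(d[1], d[2], 1L, length(idx)))
    for (i in seq_along(idx)) {
      x[, , 1L, i] <- images[[idx[i]]]
      M[, , 1L, i] <- maps[[idx[i]]]
    }
    res <- agNoGrad(dualSegFwd(net, agConst(x), agConst(M), train = FALSE))
    for (i in seq_along(idx)) {
      alpha <- matrix(res$alpha$val[, , 1L, i], d[1])
      q <- matrix(res$q$val[, , 1L, i], d[1])
      p <- if (is.null(res$p)) q else matrix(res$p$val[, , 1L, i], d[1])
      out[[idx[i]]] <- predictionTriple(alpha, p, q)
    }
  }
  out
}

coarseSegmentMany <- function(net, images, batchSize = 8L) {
  out <- vector("list", length(images))
  if (!length(images)) return(out)
  d <- dim(images[[1]])
  for (idx in chunkSeq(length(images), batchSize)) {
    x <- array(0, c(d[1], d[2], 1L, length(idx)))
    for (i in seq_along(idx)) x[, , 1L, i] <- images[[idx[i]]]
    res <- agNoGrad(coarseFwd(net, agConst(x), train = FALSE))
    for (i in seq_along(idx)) out[[idx[i]]] <- matrix(res$val[, , 1L, i], d[1])
  }
  out
}

classifyAndCamMany <- function(net, images, masks, batchSize = 8L) {
  out <- vector("list", length(images))
  if (!length(images)) return(out)
  d <- dim(images[[1]])
  w <- net$params$headW$val[2L, ]
  for (idx in chunkSeq(length(images), batchSize)) {
    x <- array(0, c(d[1], d[2], 2L, length(idx)))
    for (i in seq_along(idx)) {
      x[, , 1L, i] <- images[[idx[i]]]
      x[, , 2L, i] <- masks[[idx[i]]]
    }
    res <- agNoGrad(classifierFwd(net, agConst(x), train = FALSE))
    probs <- softmaxProbs(res$logits$val)
    fd <- dim(res$feats$val)
    for (i in seq_along(idx)) {
      fm <- matrix(res$feats$val[, , , i], fd[1] * fd[2], fd[3])
      M <- normalizeLocationMap(matrix(fm %*% w, fd[1], fd[2]))
      M <- pmin(pmax(bilinearResizeMat(M, d[1]), 0), 1)
      pr <- probs[, i]
      names(pr) <- c("absent", "present")
      out[[idx[i]]] <- list(probs = pr, locationMap = M)
    }
  }
  out
}
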
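# Loss functions: Dice overlap, hard-pixel rank hinge, their weighted sum
# (the localization loss), and the four-part segmentation loss (area BCE +
# Dice, edge BCE, detector BCE, and the symmetric branch-consistency
# divergence). Every public function accepts plain numeric rasters (and
# returns a numeric scalar) or autodiff nodes (and returns a node), so the
# same code path is exercised by the unit tests and by training.

# view a value (array or vector) as a (npix, nsamp) matrix; 4D arrays are
# treated as batches along the 4th dimension
asPixelMatrix <- function(v) {
  d <- dim(v)
  if (!is.null(d) && length(d) == 4L) {
    matrix(v, prod(d[1:3]), d[4])
  } else {
    matrix(as.vector(v), length(v), 1L)
  }
}

checkShapes <- function(a, b, what = "inputs") {
  da <- dim(a)
  db <- dim(b)
  if (length(a) != length(b) ||
      (!is.null(da) && !is.null(db) && !identical(da, db))) {
    stop(what, " must share a shape")
  }
  invisible(TRUE)
}

## ---- node builders ----------------------------------------------------

agDiceLoss <- function(alpha, beta, smooth) {
  am <- asPixelMatrix(alpha$val)
  bm <- asPixelMatrix(beta)
  ns <- ncol(am)
  A <- colSums(am * bm)
  D <- colSums(am) + colSums(bm)
  val <- mean(1 - (2 * A + smooth) / (D + smooth))
  mkNode(val, list(alpha), function(g) {
    grad <- sweep(bm, 2, -2 / (D + smooth), `*`) +
      rep((2 * A + smooth) / (D + smooth)^2, each = nrow(am))
    grad <- g * grad / ns
    dim(grad) <- if (is.null(dim(alpha$val))) NULL else dim(alpha$val)
    list(grad)
  })
}

agBCELoss <- function(alpha, y, eps, positiveOnly = FALSE) {
  am <- asPixelMatrix(alpha$val)
  ym <- asPixelMatrix(y)
  ns <- ncol(am)
  ac <- pmin(pmax(am, eps), 1 - eps)
  val <- if (positiveOnly) {
    -sum(ym * log(ac)) / ns
  } else {
    -sum(ym * log(ac) + (1 - ym) * log(1 - ac)) / ns
  }
  mkNode(val, list(alpha), function(g) {
    grad <- if (positiveOnly) -ym / ac else -ym / ac + (1 - ym) / (1 - ac)
    grad[am < eps | am > 1 - eps] <- 0  # clamp is active: flat region
    grad <- g * grad / ns
    dim(grad) <- if (is.null(dim(alpha$val))) NULL else dim(alpha$val)
    list(grad)
  })
}

agConLossNode <- function(p, q, eps) {
  pm <- asPixelMatrix(p$val)
  qm <- asPixelMatrix(q$val)
  ns <- ncol(pm)
  pc <- pmin(pmax(pm, eps), 1 - eps)
  qc <- pmin(pmax(qm, eps), 1 - eps)
  lr <- log(pc / qc)
  val <- sum((pc - qc) * lr) / ns
  mkNode(val, list(p, q), function(g) {
    dp <- lr + (pc - qc) / pc
    dq <- -lr - (pc - qc) / qc
    dp[pm < eps | pm > 1 - eps] <- 0
    dq[qm < eps | qm > 1 - eps] <- 0
    shp <- function(grad, ref) {
      grad <- g * grad / ns
      dim(grad) <- if (is.null(dim(ref))) NULL else dim(ref)
      grad
    }
    list(if (p$req) shp(dp, p$val) else NULL,
         if (q$req) shp(dq, q$val) else NULL)
  })
}

# hard-pixel selection for one image: indices of the K largest-error pixels
# in each class (error = alpha for background, 1 - alpha for tumor);
# ties broken by pixel index (stable radix order)
selectHardPixels <- function(alphaVec, betaVec, K) {
  bgIdx <- which(betaVec == 0)
  tmIdx <- which(betaVec == 1)
  kb <- min(K, length(bgIdx))
  kt <- min(K, length(tmIdx))
  ordB <- bgIdx[order(alphaVec[bgIdx], decreasing = TRUE,
                      method = "radix")][seq_len(kb)]
  ordT <- tmIdx[order(1 - alphaVec[tmIdx], decreasing = TRUE,
                      method = "radix")][seq_len(kt)]
  list(bg = ordB, tumor = ordT)
}

# rank hinge over a batch; images whose label contains a single class are
# skipped (the pairwise hinge is undefined there)
agRankLossNode <- function(alpha, beta, K, mu, strict = FALSE) {
  am <- asPixelMatrix(alpha$val)
  bm <- asPixelMatrix(beta)
  ns <- ncol(am)
  perImage <- vector("list", ns)
  vals <- numeric(0)
  for (s in seq_len(ns)) {
    av <- am[, s]
    bv <- bm[, s]
    if (!any(bv == 1) || !any(bv == 0)) {
      if (strict) stop("rank loss needs both tumor and background pixels")
      next
    }
    sel <- selectHardPixels(av, bv, K)
    B <- av[sel$bg]
    Tm <- av[sel$tumor]
    z <- outer(B, Tm, `-`) + mu
    act <- z > 0
    N <- length(B) * length(Tm)
    perImage[[s]] <- list(sel = sel, act = act, N = N)
    vals <- c(vals, sum(z[act]) / N)
  }
  used <- sum(!vapply(perImage, is.null, logical(1)))
  val <- if (used == 0) 0 else sum(vals) / used
  mkNode(val, list(alpha), function(g) {
    grad <- matrix(0, nrow(am), ns)
    for (s in seq_len(ns)) {
      pi <- perImage[[s]]
      if (is.null(pi)) next
      dB <- rowSums(pi$act) / pi$N
      dT <- -colSums(pi$act) / pi$N
      grad[pi$sel$bg, s] <- grad[pi$sel$bg, s] + dB
      grad[pi$sel$tumor, s] <- grad[pi$sel$tumor, s] + dT
    }
    grad <- g * grad / max(used, 1)
    dim(grad) <- if (is.null(dim(alpha$val))) NULL else dim(alpha$val)
    list(grad)
  })
}

# wrap a public entry point: numeric in -> numeric out, node in -> node out
lossWrap <- function(alpha, build) {
  if (isNode(alpha)) build(alpha) else build(agConst(alpha))$val
}

## ---- public losses ----------------------------------------------------

#' Dice loss
#'
#' `1 - (2 sum(alpha beta) + smooth) / (sum(alpha) + sum(beta) + smooth)`,
#' averaged over the batch for 4D inputs. Always in \[0, 1).
#'
#' @param alpha probability raster in \[0,1\] (numeric or autodiff node)
#' @param beta binary ground-truth raster
#' @param smooth small stabilizer keeping the ratio finite
#' @return numeric scalar (or scalar node for node input)
#' @export
diceLoss <- function(alpha, beta, smooth = 1e-5) {
  checkShapes(nodeValue(alpha), beta, "alpha and beta")
  lossWrap(alpha, function(a) agDiceLoss(a, beta, smooth))
}

#' Hard-pixel rank loss
#'
#' Selects the `K` background pixels with the largest error (`alpha`) and
#' the `K` tumor pixels with the largest error (`1 - alpha`) and averages
#' the hinge `max(0, B_i - T_j + mu)` over all pairs. If a class holds
#' fewer than `K` pixels, all of them are used and the normalization is the
#' actual pair count.
#'
#' @param alpha probability raster
#' @param beta binary raster with at least one tumor and one background pixel
#' @param K hard-pixel count per class
#' @param mu hinge margin
#' @return numeric scalar (or node)
#' @export
rankLoss <- function(alpha, beta, K = 30L, mu = 0.3) {
  checkShapes(nodeValue(alpha), beta, "alpha and beta")
  lossWrap(alpha, function(a) agRankLossNode(a, beta, K, mu, strict = TRUE))
}

#' Localization loss: Dice plus weighted rank loss
#'
#' @param alpha,beta as in [diceLoss()] and [rankLoss()]
#' @param config a [LocLossConfig-class]
#' @return numeric scalar (or node)
#' @export
locLoss <- function(alpha, beta, config = locLossConfig()) {
  checkShapes(nodeValue(alpha), beta, "alpha and beta")
  lossWrap(alpha, function(a) {
    agScalarComb(list(agDiceLoss(a, beta, config@smooth),
                      agRankLossNode(a, beta, config@K, config@mu,
                                     strict = TRUE)),
                 c(1, config@lambda1))
  })
}

#' Area loss: pixel-summed binary cross-entropy plus Dice loss
#'
#' The cross-entropy includes both classes by default; set
#' `positiveOnly = TRUE` in the config for the one-sided literal form (which
#' is degenerate on its own: it is minimized by predicting 1 everywhere).
#'
#' @param alpha area probability raster
#' @param normal binary whole-tumor label
#' @param config a [SegLossConfig-class]
#' @return numeric scalar (or node)
#' @export
areaLoss <- function(alpha, normal, config = segLossConfig()) {
  checkShapes(nodeValue(alpha), normal, "alpha and normal")
  lossWrap(alpha, function(a) {
    agScalarComb(list(
      agBCELoss(a, normal, config@clampEps, config@positiveOnly),
      agDiceLoss(a, normal, config@smooth)))
  })
}

#' Edge and detector losses: pixel-summed binary cross-entropy
#'
#' `edgeLoss` supervises the edge decoding branch; `edLoss` supervises the
#' boundary-detector output. Both compare a probability map against the
#' boundary label with the same clamped cross-entropy.
#'
#' @param p,q probability rasters
#' @param boundary binary tumor-rim label
#' @param config a [SegLossConfig-class]
#' @return numeric scalar (or node)
#' @export
edgeLoss <- function(p, boundary, config = segLossConfig()) {
  checkShapes(nodeValue(p), boundary, "p and boundary")
  lossWrap(p, function(a) {
    agBCELoss(a, boundary, config@clampEps, config@positiveOnly)
  })
}

#' @rdname edgeLoss
#' @export
edLoss <- function(q, boundary, config = segLossConfig()) {
  checkShapes(nodeValue(q), boundary, "q and boundary")
  lossWrap(q, function(a) {
    agBCELoss(a, boundary, config@clampEps, config@positiveOnly)
  })
}

#' Branch-consistency loss (symmetric divergence between the two decoders)
#'
#' `-sum p log(q/p) - sum q log(p/q) = sum (p - q) log(p/q) >= 0`, zero iff
#' the two maps agree after clamping.
#'
#' @param p,q probability rasters (numeric or nodes)
#' @param config a [SegLossConfig-class]
#' @return numeric scalar (or node)
#' @export
conLoss <- function(p, q, config = segLossConfig()) {
  checkShapes(nodeValue(p), nodeValue(q), "p and q")
  if (isNode(p) || isNode(q)) {
    agConLossNode(asNode(p), asNode(q), config@clampEps)
  } else {
    agConLossNode(agConst(p), agConst(q), config@clampEps)$val
  }
}

#' The full four-part segmentation loss
#'
#' `L = L_area + L_edge + L_ed + lambda2 * L_con`, with the per-term
#' breakdown reported for logging and tests.
#'
#' @param preds a [PredictionTriple-class] (or list with elements
#'   `alpha`, `p`, `q`, numeric or nodes)
#' @param sample an [ImageSample-class] supplying `normalLabel` and
#'   `boundaryLabel` (or a list with those elements)
#' @param config a [SegLossConfig-class]
#' @return list with `total`, `area`, `edge`, `ed`, `con` (numerics, or
#'   nodes for node input)
#' @export
segLoss <- function(preds, sample, config = segLossConfig()) {
  alpha <- if (is(preds, "PredictionTriple")) preds@alpha else preds$alpha
  p <- if (is(preds, "PredictionTriple")) preds@p else preds$p
  q <- if (is(preds, "PredictionTriple")) preds@q else preds$q
  normal <- if (is(sample, "ImageSample")) normalLabel(sample) else sample$normal
  boundary <- if (is(sample, "ImageSample")) boundaryLabel(sample) else sample$boundary
  terms <- list(
    area = areaLoss(alpha, normal, config),
    edge = edgeLoss(p, boundary, config),
    ed = edLoss(q, boundary, config),
    con = conLoss(p, q, config)
  )
  anyNode <- any(vapply(terms, isNode, logical(1)))
  total <- if (anyNode) {
    agScalarComb(lapply(terms, asNode), c(1, 1, 1, config@lambda2))
  } else {
    terms$area + terms$edge + terms$ed + config@lambda2 * terms$con
  }
  c(list(total = total), terms)
}
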
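# Minimal reverse-mode automatic differentiation over dense arrays.
# Tensors are R arrays with dim (h, w, c, n); fully-connected stages use
# (c, n) matrices and losses are length-1 scalars. Each node stores its
# value, its parents and a closure mapping the output gradient to parent
# gradients. Compiled kernels (src/ops.cpp) back the convolution, pooling
# and resizing primitives.

.ag <- new.env(parent = emptyenv())
.ag$enabled <- TRUE
.ag$counter <- 0L

agNode <- function(val, parents = list(), bfun = NULL, req = NULL) {
  e <- new.env(parent = emptyenv())
  .ag$counter <- .ag$counter + 1L
  e$id <- .ag$counter
  e$val <- val
  e$parents <- parents
  e$bfun <- bfun
  e$req <- if (is.null(req)) {
    any(vapply(parents, function(p) p$req, logical(1)))
  } else req
  e$grad <- NULL
  class(e) <- "agNode"
  e
}

agConst <- function(val) agNode(val, req = FALSE)
agParam <- function(val) agNode(val, req = TRUE)
isNode <- function(x) inherits(x, "agNode")
asNode <- function(x) if (isNode(x)) x else agConst(x)
nodeValue <- function(x) if (isNode(x)) x$val else x

# create a recording node only when gradients are wanted
mkNode <- function(val, parents, bfun) {
  if (.ag$enabled && any(vapply(parents, function(p) p$req, logical(1)))) {
    agNode(val, parents, bfun)
  } else {
    agNode(val, req = FALSE)
  }
}

agNoGrad <- function(expr) {
  old <- .ag$enabled
  .ag$enabled <- FALSE
  on.exit(.ag$enabled <- old)
  expr
}

agBackward <- function(root) {
  stopifnot(isNode(root), length(root$val) == 1L)
  topo <- vector("list", 256L)
  ntopo <- 0L
  visited <- new.env(hash = TRUE, parent = emptyenv())
  visit <- function(nd) {
    key <- as.character(nd$id)
    if (!is.null(visited[[key]])) return(invisible())
    assign(key, TRUE, envir = visited)
    for (p in nd$parents) if (p$req) visit(p)
    ntopo <<- ntopo + 1L
    if (ntopo > length(topo)) length(topo) <<- 2L * ntopo
    topo[[ntopo]] <<- nd
    invisible()
  }
  visit(root)
  root$grad <- 1
  for (i in rev(seq_len(ntopo))) {
    nd <- topo[[i]]
    if (is.null(nd$bfun) || is.null(nd$grad)) next
    gs <- nd$bfun(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      pk <- ps[[k]]
      if (!pk$req || is.null(gs[[k]])) next
      pk$grad <- if (is.null(pk$grad)) gs[[k]] else pk$grad + gs[[k]]
    }
  }
  invisible(root)
}

agZeroGrad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

## ---- tensor primitives -----------------------------------------------

# 2D convolution, stride 1, zero "same" padding by default.
# x: (h,w,cin,n); W: (k,k,cin,cout); b: length cout
agConv2d <- function(x, W, b, pad = NULL) {
  wd <- dim(W$val)
  stopifnot(dim(x$val)[3] == wd[3])
  k <- wd[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  y <- conv2d_fwd_cpp(x$val, W$val, b$val, as.integer(pad))
  mkNode(y, list(x, W, b), function(g) {
    r <- conv2d_bwd_cpp(x$val, W$val, g, as.integer(pad), x$req, W$req)
    list(r$dx, r$dW, if (b$req) r$db else NULL)
  })
}

# batch normalization over (h,w,n) per channel; running stats in `layer`.
# When .ag$bnCollect is set, batch statistics are accumulated exactly
# (for the post-training recalibration pass) instead of the running update.
agBatchNorm <- function(x, gamma, beta, layer, train) {
  eps <- 1e-5
  if (train) {
    st <- bn_stats_cpp(x$val)
    mu <- st$mean
    va <- st$var
    if (isTRUE(.ag$bnCollect)) {
      layer$buffers$accMean <- (layer$buffers$accMean %||% 0) + mu
      layer$buffers$accVar <- (layer$buffers$accVar %||% 0) + va
      layer$buffers$accN <- (layer$buffers$accN %||% 0) + 1
    } else {
      layer$buffers$runMean <- 0.9 * layer$buffers$runMean + 0.1 * mu
      layer$buffers$runVar <- 0.9 * layer$buffers$runVar + 0.1 * va
    }
  } else {
    mu <- layer$buffers$runMean
    va <- layer$buffers$runVar
  }
  invstd <- 1 / sqrt(va + eps)
  y <- bn_apply_cpp(x$val, gamma$val, beta$val, mu, invstd)
  mkNode(y, list(x, gamma, beta), function(g) {
    r <- bn_bwd_cpp(x$val, g, gamma$val, mu, invstd, train)
    list(if (x$req) r$dx else NULL,
         if (gamma$req) r$dgamma else NULL,
         if (beta$req) r$dbeta else NULL)
  })
}

agRelu <- function(x) {
  y <- relu_fwd_cpp(x$val)
  mkNode(y, list(x), function(g) list(relu_bwd_cpp(x$val, g)))
}

agSigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$val))
  mkNode(y, list(x), function(g) list(g * y * (1 - y)))
}

agMaxPool2 <- function(x) {
  res <- maxpool2_fwd_cpp(x$val)
  xd <- dim(x$val)
  mkNode(res$y, list(x), function(g) {
    list(maxpool2_bwd_cpp(g, res$idx, xd))
  })
}

agResize <- function(x, oh, ow) {
  d <- dim(x$val)
  if (d[1] == oh && d[2] == ow) return(x)
  y <- bilinear_fwd_cpp(x$val, as.integer(oh), as.integer(ow))
  mkNode(y, list(x), function(g) list(bilinear_bwd_cpp(g, d[1], d[2])))
}

# concatenate along the channel dimension
agConcat <- function(nodes) {
  ds <- lapply(nodes, function(n) dim(n$val))
  h <- ds[[1]][1]; w <- ds[[1]][2]; n <- ds[[1]][4]
  cs <- vapply(ds, `[`, numeric(1), 3)
  y <- array(0, c(h, w, sum(cs), n))
  off <- 0L
  for (i in seq_along(nodes)) {
    y[, , off + seq_len(cs[i]), ] <- nodes[[i]]$val
    off <- off + cs[i]
  }
  mkNode(y, nodes, function(g) {
    out <- vector("list", length(nodes))
    off <- 0L
    for (i in seq_along(nodes)) {
      out[[i]] <- g[, , off + seq_len(cs[i]), , drop = FALSE]
      off <- off + cs[i]
    }
    out
  })
}

# multiply every channel of x by a single-channel spatial gate g
agMulGate <- function(x, gate) {
  d <- dim(x$val)
  cc <- d[3]
  garr <- gate$val[, , rep(1L, cc), , drop = FALSE]
  y <- x$val * garr
  mkNode(y, list(x, gate), function(g) {
    dx <- if (x$req) g * garr else NULL
    dg <- NULL
    if (gate$req) {
      arr <- g * x$val
      dim(arr) <- c(d[1] * d[2], cc, d[4])
      dgm <- colSums(aperm(arr, c(2, 1, 3)))
      dg <- array(dgm, c(d[1], d[2], 1L, d[4]))
    }
    list(dx, dg)
  })
}

# depth-wise convolution with per-sample kernels (dynamic filters)
agDwConv <- function(f, k) {
  s <- dim(k$val)[1]
  y <- dwconv_fwd_cpp(f$val, k$val)
  mkNode(y, list(f, k), function(g) {
    df <- if (f$req) dwconv_bwd_f_cpp(g, k$val) else NULL
    dk <- if (k$req) dwconv_bwd_k_cpp(g, f$val, s) else NULL
    list(df, dk)
  })
}

# static depth-wise convolution: one (s,s,c) kernel shared across the batch
agDwConvStatic <- function(x, Wd) {
  d <- dim(x$val)
  n <- d[4]
  wd <- dim(Wd$val)
  krep <- array(rep(Wd$val, n), c(wd[1], wd[2], wd[3], n))
  y <- dwconv_fwd_cpp(x$val, krep)
  mkNode(y, list(x, Wd), function(g) {
    dx <- if (x$req) dwconv_bwd_f_cpp(g, krep) else NULL
    dW <- NULL
    if (Wd$req) {
      dk <- dwconv_bwd_k_cpp(g, x$val, wd[1])
      dim(dk) <- c(wd[1] * wd[2] * wd[3], n)
      dW <- array(rowSums(dk), wd)
    }
    list(dx, dW)
  })
}

agAdaMaxPool <- function(x, s) {
  res <- adamaxpool_fwd_cpp(x$val, as.integer(s))
  xd <- dim(x$val)
  mkNode(res$y, list(x), function(g) {
    list(adamaxpool_bwd_cpp(g, res$idx, xd))
  })
}

# global average pooling: (h,w,c,n) -> (c,n)
agGAP <- function(x) {
  d <- dim(x$val)
  hw <- d[1] * d[2]
  a <- x$val
  dim(a) <- c(hw, d[3], d[4])
  y <- colMeans(a, dims = 1)
  if (is.null(dim(y))) y <- matrix(y, d[3], d[4])
  mkNode(y, list(x), function(g) {
    dx <- rep(as.vector(g), each = hw) / hw
    dim(dx) <- d
    list(dx)
  })
}

# z: (cin,n); W: (cout,cin); b: length cout
agLinear <- function(z, W, b) {
  y <- W$val %*% z$val + b$val
  mkNode(y, list(z, W, b), function(g) {
    list(
      if (z$req) crossprod(W$val, g) else NULL,
      if (W$req) tcrossprod(g, z$val) else NULL,
      if (b$req) rowSums(g) else NULL
    )
  })
}

# mean cross-entropy of softmax(logits) against 1-based integer labels
agSoftmaxCE <- function(logits, labels) {
  lv <- logits$val
  n <- ncol(lv)
  mx <- apply(lv, 2, max)
  ex <- exp(sweep(lv, 2, mx))
  probs <- sweep(ex, 2, colSums(ex), `/`)
  pick <- probs[cbind(labels, seq_len(n))]
  val <- -mean(log(pmax(pick, 1e-12)))
  mkNode(val, list(logits), function(g) {
    d <- probs
    d[cbind(labels, seq_len(n))] <- d[cbind(labels, seq_len(n))] - 1
    list(g * d / n)
  })
}

softmaxProbs <- function(logits) {
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  sweep(ex, 2, colSums(ex), `/`)
}

# weighted sum of scalar nodes
agScalarComb <- function(nodes, weights = rep(1, length(nodes))) {
  val <- sum(vapply(nodes, function(n) n$val, numeric(1)) * weights)
  mkNode(val, nodes, function(g) as.list(g * weights))
}

## ---- module containers -----------------------------------------------

newModule <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$buffers <- list()
  e$children <- list()
  class(e) <- "agModule"
  e
}

moduleParams <- function(m) {
  out <- m$params
  for (nm in names(m$children)) {
    ch <- moduleParams(m$children[[nm]])
    if (length(ch)) names(ch) <- paste(nm, names(ch), sep = ".")
    out <- c(out, ch)
  }
  out
}

moduleState <- function(m) {
  ps <- moduleParams(m)
  list(
    params = lapply(ps, function(p) p$val),
    buffers = moduleBuffers(m)
  )
}

moduleBuffers <- function(m) {
  out <- m$buffers
  for (nm in names(m$children)) {
    ch <- moduleBuffers(m$children[[nm]])
    if (length(ch)) names(ch) <- paste(nm, names(ch), sep = ".")
    out <- c(out, ch)
  }
  out
}

loadModuleState <- function(m, state) {
  ps <- moduleParams(m)
  stopifnot(identical(sort(names(ps)), sort(names(state$params))))
  for (nm in names(ps)) ps[[nm]]$val <- state$params[[nm]]
  assignBuffers(m, state$buffers)
  invisible(m)
}

assignBuffers <- function(m, buffers) {
  for (nm in names(m$buffers)) {
    if (!is.null(buffers[[nm]])) m$buffers[[nm]] <- buffers[[nm]]
  }
  for (nm in names(m$children)) {
    keep <- startsWith(names(buffers), paste0(nm, "."))
    subbuf <- buffers[keep]
    names(subbuf) <- substring(names(subbuf), nchar(nm) + 2L)
    assignBuffers(m$children[[nm]], subbuf)
  }
  invisible(m)
}


# freeze normalization statistics as the exact average of batch statistics
# over forward passes executed inside `expr` (training-mode forwards)
bnRecalibrate <- function(mod, expr) {
  walk <- function(m, f) {
    if (identical(m$type, "bn")) f(m)
    for (ch in m$children) walk(ch, f)
  }
  walk(mod, function(m) {
    m$buffers$accMean <- NULL
    m$buffers$accVar <- NULL
    m$buffers$accN <- NULL
  })
  .ag$bnCollect <- TRUE
  on.exit(.ag$bnCollect <- FALSE)
  force(expr)
  walk(mod, function(m) {
    if (!is.null(m$buffers$accN) && m$buffers$accN > 0) {
      m$buffers$runMean <- m$buffers$accMean / m$buffers$accN
      m$buffers$runVar <- m$buffers$accVar / m$buffers$accN
    }
    m$buffers$accMean <- NULL
    m$buffers$accVar <- NULL
    m$buffers$accN <- NULL
  })
  invisible(mod)
}

## ---- optimizer --------------------------------------------------------

# SGD with momentum and decoupled-in-gradient weight decay
sgdStep <- function(params, state, lr, momentum, weightDecay) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad + weightDecay * p$val
    v <- state[[nm]]
    v <- if (is.null(v)) g else momentum * v + g
    state[[nm]] <- v
    p$val <- p$val - lr * v
    p$grad <- NULL
  }
  state
}
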
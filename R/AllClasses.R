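#' @import methods
NULL

## ---- PhantomConfig ----------------------------------------------------

#' Configuration for the synthetic phantom generator
#'
#' Describes the statistical structure of the synthetic nonenhanced-MRI-like
#' phantoms: image geometry, tumor count/size ranges, the (deliberately low)
#' tumor/background intensity contrast, edge blur, additive noise and
#' tumor-like background distractors.
#'
#' `tumorRadiusRange` is interpreted as the *equivalent* radius of an
#' elliptical tumor: axes are \eqn{a = r/\sqrt{\rho}}, \eqn{b = r\sqrt{\rho}}
#' for a random axis ratio \eqn{\rho \in [0.5, 1]}, so the lesion area is
#' \eqn{\pi r^2} regardless of eccentricity.
#'
#' @slot imageSize pixels per side (>= 32, divisible by 16)
#' @slot nTumorsRange integer interval for the number of tumors per image
#' @slot tumorRadiusRange equivalent-radius interval in pixels
#' @slot tumorContrast tumor-over-background intensity offset in (0,1)
#' @slot edgeBlurSigma Gaussian blur (pixels) applied to the tumor edge
#' @slot noiseSigma additive Gaussian noise scale
#' @slot nDistractorsRange integer interval for tumor-like distractor blobs
#' @slot distractorContrast intensity offset of distractors in (0,1)
#' @slot seed base random seed
#' @exportClass PhantomConfig
setClass("PhantomConfig", representation(
  imageSize = "integer",
  nTumorsRange = "integer",
  tumorRadiusRange = "numeric",
  tumorContrast = "numeric",
  edgeBlurSigma = "numeric",
  noiseSigma = "numeric",
  nDistractorsRange = "integer",
  distractorContrast = "numeric",
  seed = "integer"
))

setValidity("PhantomConfig", function(object) {
  msgs <- character()
  if (length(object@imageSize) != 1L || object@imageSize < 32L ||
      object@imageSize %% 16L != 0L) {
    msgs <- c(msgs, "imageSize: must be a single integer >= 32 and divisible by 16")
  }
  chkRange <- function(x, nm, integer = FALSE) {
    if (length(x) != 2L || any(is.na(x)) || x[1] > x[2]) {
      return(sprintf("%s: must be a non-empty interval c(lo, hi)", nm))
    }
    character()
  }
  msgs <- c(msgs, chkRange(object@nTumorsRange, "nTumorsRange"))
  msgs <- c(msgs, chkRange(object@tumorRadiusRange, "tumorRadiusRange"))
  msgs <- c(msgs, chkRange(object@nDistractorsRange, "nDistractorsRange"))
  if (length(object@nTumorsRange) == 2L && any(object@nTumorsRange < 0L)) {
    msgs <- c(msgs, "nTumorsRange: must be non-negative")
  }
  if (length(object@tumorRadiusRange) == 2L &&
      object@tumorRadiusRange[2] >= object@imageSize / 2) {
    msgs <- c(msgs, "tumorRadiusRange: max must be < imageSize/2")
  }
  if (object@tumorContrast <= 0 || object@tumorContrast >= 1) {
    msgs <- c(msgs, "tumorContrast: must lie in (0, 1)")
  }
  if (object@distractorContrast <= 0 || object@distractorContrast >= 1) {
    msgs <- c(msgs, "distractorContrast: must lie in (0, 1)")
  }
  if (object@edgeBlurSigma < 0) msgs <- c(msgs, "edgeBlurSigma: must be >= 0")
  if (object@noiseSigma < 0) msgs <- c(msgs, "noiseSigma: must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Create a phantom generator configuration
#'
#' Defaults emulate the target imaging regime: low tumor/background contrast
#' (0.08 intensity units), blurred tumor margins, tumor equivalent radii
#' spanning small (5 px) to large (45 px) at a 256-px field of view, and a
#' handful of lower-contrast tumor-like distractors.
#'
#' @param imageSize,nTumorsRange,tumorRadiusRange,tumorContrast,edgeBlurSigma
#'   see the class slots
#' @param noiseSigma,nDistractorsRange,distractorContrast,seed see the class
#'   slots
#' @return a validated [PhantomConfig-class] object
#' @examples
#' cfg <- phantomConfig(imageSize = 64, tumorRadiusRange = c(4, 12))
#' @export
phantomConfig <- function(imageSize = 256L,
                          nTumorsRange = c(1L, 3L),
                          tumorRadiusRange = c(5, 45),
                          tumorContrast = 0.08,
                          edgeBlurSigma = 1.5,
                          noiseSigma = 0.02,
                          nDistractorsRange = c(2L, 6L),
                          distractorContrast = 0.04,
                          seed = 1L) {
  new("PhantomConfig",
      imageSize = as.integer(imageSize),
      nTumorsRange = as.integer(nTumorsRange),
      tumorRadiusRange = as.numeric(tumorRadiusRange),
      tumorContrast = tumorContrast,
      edgeBlurSigma = edgeBlurSigma,
      noiseSigma = noiseSigma,
      nDistractorsRange = as.integer(nDistractorsRange),
      distractorContrast = distractorContrast,
      seed = as.integer(seed))
}

#' @rdname phantomConfig
#' @param ... overrides passed to [phantomConfig()]
#' @details `deskPhantomConfig()` is the CPU-scale profile: the same
#'   contrast/noise/distractor regime at a 64-px field of view, with tumor
#'   radii rescaled accordingly.
#' @export
deskPhantomConfig <- function(...) {
  args <- list(...)
  defaults <- list(imageSize = 64L, nTumorsRange = c(1L, 2L),
                   tumorRadiusRange = c(4, 12), edgeBlurSigma = 1,
                   nDistractorsRange = c(1L, 4L))
  defaults[names(args)] <- args
  do.call(phantomConfig, defaults)
}

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf("PhantomConfig: %dx%d px, tumors %d-%d (r %.1f-%.1f px, contrast %.3f),\n",
              object@imageSize, object@imageSize,
              object@nTumorsRange[1], object@nTumorsRange[2],
              object@tumorRadiusRange[1], object@tumorRadiusRange[2],
              object@tumorContrast))
  cat(sprintf("  blur sigma %.2f, noise %.3f, distractors %d-%d (contrast %.3f)\n",
              object@edgeBlurSigma, object@noiseSigma,
              object@nDistractorsRange[1], object@nDistractorsRange[2],
              object@distractorContrast))
})

## ---- ImageSample ------------------------------------------------------

#' One phantom or clinical slice with its labels
#'
#' Bundles a grayscale image with its whole-tumor mask ("normal label"),
#' tumor-rim mask ("boundary label") and image-level class label. Filling
#' the boundary label recovers the normal label for simply connected tumors.
#'
#' @slot image numeric matrix with intensities in \[0,1\]
#' @slot normalLabel 0/1 integer matrix marking the whole tumor
#' @slot boundaryLabel 0/1 integer matrix marking the tumor rim
#' @slot classLabel "present" or "absent"
#' @slot sampleID character identifier, encodes the subject
#' @exportClass ImageSample
setClass("ImageSample", representation(
  image = "matrix",
  normalLabel = "matrix",
  boundaryLabel = "matrix",
  classLabel = "character",
  sampleID = "character"
))

setValidity("ImageSample", function(object) {
  msgs <- character()
  if (!identical(dim(object@image), dim(object@normalLabel)) ||
      !identical(dim(object@image), dim(object@boundaryLabel))) {
    msgs <- c(msgs, "image, normalLabel and boundaryLabel must share a shape")
  }
  if (!all(object@normalLabel %in% c(0L, 1L)) ||
      !all(object@boundaryLabel %in% c(0L, 1L))) {
    msgs <- c(msgs, "labels must be binary 0/1")
  }
  if (!object@classLabel %in% c("present", "absent")) {
    msgs <- c(msgs, "classLabel must be 'present' or 'absent'")
  }
  hasTumor <- any(object@normalLabel > 0L)
  if (hasTumor != (object@classLabel == "present")) {
    msgs <- c(msgs, "normalLabel must be nonzero iff classLabel == 'present'")
  }
  if (any(object@boundaryLabel > object@normalLabel)) {
    msgs <- c(msgs, "boundaryLabel must be a subset of normalLabel")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname ImageSample-class
#' @param image,normalLabel,boundaryLabel,classLabel,sampleID slot values
#' @export
imageSample <- function(image, normalLabel, boundaryLabel, classLabel,
                        sampleID) {
  new("ImageSample", image = image,
      normalLabel = matrix(as.integer(normalLabel), nrow(image)),
      boundaryLabel = matrix(as.integer(boundaryLabel), nrow(image)),
      classLabel = classLabel, sampleID = sampleID)
}

setMethod("show", "ImageSample", function(object) {
  cat(sprintf("ImageSample '%s': %dx%d, class %s, %d tumor px (%d rim px)\n",
              object@sampleID, nrow(object@image), ncol(object@image),
              object@classLabel, sum(object@normalLabel),
              sum(object@boundaryLabel)))
})

#' Accessors for ImageSample
#'
#' @param x an [ImageSample-class]
#' @return the image matrix, a 0/1 label matrix, the class label string or
#'   the sample identifier
#' @name ImageSample-accessors
#' @aliases sampleImage normalLabel boundaryLabel sampleClass sampleID
NULL

#' @rdname ImageSample-accessors
#' @export
setGeneric("sampleImage", function(x) standardGeneric("sampleImage"))
#' @rdname ImageSample-accessors
#' @export
setGeneric("normalLabel", function(x) standardGeneric("normalLabel"))
#' @rdname ImageSample-accessors
#' @export
setGeneric("boundaryLabel", function(x) standardGeneric("boundaryLabel"))
#' @rdname ImageSample-accessors
#' @export
setGeneric("sampleClass", function(x) standardGeneric("sampleClass"))
#' @rdname ImageSample-accessors
#' @export
setGeneric("sampleID", function(x) standardGeneric("sampleID"))

setMethod("sampleImage", "ImageSample", function(x) x@image)
setMethod("normalLabel", "ImageSample", function(x) x@normalLabel)
setMethod("boundaryLabel", "ImageSample", function(x) x@boundaryLabel)
setMethod("sampleClass", "ImageSample", function(x) x@classLabel)
setMethod("sampleID", "ImageSample", function(x) x@sampleID)

## ---- PredictionTriple -------------------------------------------------

#' The three probability maps predicted for one image
#'
#' `alpha` is the tumor-area probability map from the main decoding branch,
#' `p` the tumor-boundary probability map from the edge decoding branch and
#' `q` the boundary map recovered from the area prediction by the small
#' boundary-detector network.
#'
#' @slot alpha,p,q numeric matrices in \[0,1\], shared shape
#' @exportClass PredictionTriple
setClass("PredictionTriple", representation(
  alpha = "matrix", p = "matrix", q = "matrix"
))

setValidity("PredictionTriple", function(object) {
  msgs <- character()
  if (!identical(dim(object@alpha), dim(object@p)) ||
      !identical(dim(object@alpha), dim(object@q))) {
    msgs <- c(msgs, "alpha, p, q must share a shape")
  }
  rng <- range(object@alpha, object@p, object@q)
  if (rng[1] < 0 || rng[2] > 1) msgs <- c(msgs, "maps must lie in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' @rdname PredictionTriple-class
#' @param alpha,p,q probability matrices
#' @export
predictionTriple <- function(alpha, p, q) {
  new("PredictionTriple", alpha = alpha, p = p, q = q)
}

setMethod("show", "PredictionTriple", function(object) {
  cat(sprintf("PredictionTriple %dx%d: mean alpha %.3f, p %.3f, q %.3f\n",
              nrow(object@alpha), ncol(object@alpha), mean(object@alpha),
              mean(object@p), mean(object@q)))
})

#' @rdname PredictionTriple-class
#' @param x a `PredictionTriple`
#' @export
setGeneric("areaMap", function(x) standardGeneric("areaMap"))
#' @rdname PredictionTriple-class
#' @export
setGeneric("edgeMap", function(x) standardGeneric("edgeMap"))
#' @rdname PredictionTriple-class
#' @export
setGeneric("detectorMap", function(x) standardGeneric("detectorMap"))
setMethod("areaMap", "PredictionTriple", function(x) x@alpha)
setMethod("edgeMap", "PredictionTriple", function(x) x@p)
setMethod("detectorMap", "PredictionTriple", function(x) x@q)

## ---- ConfusionCounts --------------------------------------------------

#' Pixelwise confusion counts
#'
#' True/false positive/negative pixel tallies for a thresholded prediction
#' against a binary truth mask; the positive class is tumor.
#'
#' @slot tp,fp,tn,fn non-negative counts
#' @exportClass ConfusionCounts
setClass("ConfusionCounts", representation(
  tp = "numeric", fp = "numeric", tn = "numeric", fn = "numeric"
))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(v < 0) || any(v != floor(v))) {
    "tp, fp, tn, fn must be non-negative integers"
  } else TRUE
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: tp=%g fp=%g tn=%g fn=%g (n=%g)\n",
              object@tp, object@fp, object@tn, object@fn,
              object@tp + object@fp + object@tn + object@fn))
})

## ---- split / loss / network / train configs --------------------------

#' Dataset split plan
#'
#' @slot trainFraction proportion of data assigned to training (0,1)
#' @slot foldCount number of cross-validation folds (>= 1)
#' @slot bySubject keep all images of a subject in one partition
#' @slot seed shuffling seed
#' @exportClass SplitPlan
setClass("SplitPlan", representation(
  trainFraction = "numeric", foldCount = "integer",
  bySubject = "logical", seed = "integer"
))

setValidity("SplitPlan", function(object) {
  msgs <- character()
  if (object@trainFraction <= 0 || object@trainFraction >= 1) {
    msgs <- c(msgs, "trainFraction must lie in (0, 1)")
  }
  if (object@foldCount < 1L) msgs <- c(msgs, "foldCount must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SplitPlan-class
#' @param trainFraction,foldCount,bySubject,seed see slots
#' @export
splitPlan <- function(trainFraction = 0.8, foldCount = 1L,
                      bySubject = TRUE, seed = 1L) {
  new("SplitPlan", trainFraction = trainFraction,
      foldCount = as.integer(foldCount), bySubject = bySubject,
      seed = as.integer(seed))
}

#' Localization-loss hyperparameters
#'
#' Dice overlap term plus a hard-pixel rank term: `lambda1` weights the rank
#' loss, `K` is the number of hardest pixels selected per class and `mu` the
#' hinge margin between hard background and hard tumor pixels.
#'
#' @slot smooth,lambda1,K,mu see description
#' @exportClass LocLossConfig
setClass("LocLossConfig", representation(
  smooth = "numeric", lambda1 = "numeric", K = "integer", mu = "numeric"
))

setValidity("LocLossConfig", function(object) {
  msgs <- character()
  if (object@smooth <= 0) msgs <- c(msgs, "smooth must be > 0")
  if (object@K < 1L) msgs <- c(msgs, "K must be >= 1")
  if (object@mu < 0) msgs <- c(msgs, "mu must be >= 0")
  if (object@lambda1 < 0) msgs <- c(msgs, "lambda1 must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname LocLossConfig-class
#' @param smooth,lambda1,K,mu see slots
#' @export
locLossConfig <- function(smooth = 1e-5, lambda1 = 0.05, K = 30L, mu = 0.3) {
  new("LocLossConfig", smooth = smooth, lambda1 = lambda1,
      K = as.integer(K), mu = mu)
}

#' Segmentation-loss hyperparameters
#'
#' @slot lambda2 weight of the branch-consistency (divergence) term
#' @slot smooth Dice stabilizer
#' @slot clampEps probability clamp protecting the logarithms
#' @slot positiveOnly use the positive-class-only cross-entropy literal form
#' @exportClass SegLossConfig
setClass("SegLossConfig", representation(
  lambda2 = "numeric", smooth = "numeric", clampEps = "numeric",
  positiveOnly = "logical"
))

setValidity("SegLossConfig", function(object) {
  msgs <- character()
  if (object@lambda2 < 0) msgs <- c(msgs, "lambda2 must be >= 0")
  if (object@clampEps <= 0 || object@clampEps >= 0.5) {
    msgs <- c(msgs, "clampEps must lie in (0, 0.5)")
  }
  if (object@smooth <= 0) msgs <- c(msgs, "smooth must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SegLossConfig-class
#' @param lambda2,smooth,clampEps,positiveOnly see slots
#' @export
segLossConfig <- function(lambda2 = 0.5, smooth = 1e-5, clampEps = 1e-7,
                          positiveOnly = FALSE) {
  new("SegLossConfig", lambda2 = lambda2, smooth = smooth,
      clampEps = clampEps, positiveOnly = positiveOnly)
}

#' Bottleneck multiscale module configuration
#'
#' @slot kernelSizes odd dynamic-kernel sizes (default 1, 3, 5)
#' @slot reducedChannels reduced channel count c' (NA means c/2)
#' @slot outChannels channels of the aggregated output
#' @exportClass BMMConfig
setClass("BMMConfig", representation(
  kernelSizes = "integer", reducedChannels = "integer", outChannels = "integer"
))

setValidity("BMMConfig", function(object) {
  msgs <- character()
  if (length(object@kernelSizes) < 1L || any(object@kernelSizes < 1L) ||
      any(object@kernelSizes %% 2L == 0L)) {
    msgs <- c(msgs, "kernelSizes must be odd and >= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname BMMConfig-class
#' @param kernelSizes,reducedChannels,outChannels see slots
#' @export
bmmConfig <- function(kernelSizes = c(1L, 3L, 5L), reducedChannels = NA_integer_,
                      outChannels = NA_integer_) {
  new("BMMConfig", kernelSizes = as.integer(kernelSizes),
      reducedChannels = as.integer(reducedChannels),
      outChannels = as.integer(outChannels))
}

#' Network architecture configuration
#'
#' `baseChannels` is the stage-1 encoder width (doubled at each of the five
#' encoder stages); ablation switches mirror the removable components:
#' spatial gates, the bottleneck multiscale module, the location-map input,
#' the edge decoding branch and the dense upward connections.
#'
#' @slot baseChannels encoder stage-1 width (paper profile 32; small test
#'   profile 8)
#' @slot depth encoder stages (fixed 5)
#' @slot classifier "separable" compact classifier (default)
#' @slot miniUnetDepth levels in the boundary detector
#' @slot upsampleMode "bilinear+conv"
#' @slot kernelSizes dynamic-kernel sizes of the multiscale bottleneck
#' @slot useSSE,useBMM,useLocationMap,useEdgeBranch,denseUpward ablation flags
#' @exportClass NetworkConfig
setClass("NetworkConfig", representation(
  baseChannels = "integer", depth = "integer", classifier = "character",
  miniUnetDepth = "integer", upsampleMode = "character",
  kernelSizes = "integer", useSSE = "logical", useBMM = "logical",
  useLocationMap = "logical", useEdgeBranch = "logical",
  denseUpward = "logical"
))

setValidity("NetworkConfig", function(object) {
  msgs <- character()
  if (object@baseChannels < 4L) msgs <- c(msgs, "baseChannels must be >= 4")
  if (object@depth != 5L) msgs <- c(msgs, "depth is fixed at 5")
  if (length(msgs)) msgs else TRUE
})

#' @rdname NetworkConfig-class
#' @param baseChannels,depth,classifier,miniUnetDepth,upsampleMode see slots
#' @param kernelSizes,useSSE,useBMM,useLocationMap,useEdgeBranch,denseUpward
#'   see slots
#' @export
networkConfig <- function(baseChannels = 32L, depth = 5L,
                          classifier = "separable", miniUnetDepth = 2L,
                          upsampleMode = "bilinear+conv",
                          kernelSizes = c(1L, 3L, 5L),
                          useSSE = TRUE, useBMM = TRUE,
                          useLocationMap = TRUE, useEdgeBranch = TRUE,
                          denseUpward = TRUE) {
  new("NetworkConfig", baseChannels = as.integer(baseChannels),
      depth = as.integer(depth), classifier = classifier,
      miniUnetDepth = as.integer(miniUnetDepth), upsampleMode = upsampleMode,
      kernelSizes = as.integer(kernelSizes), useSSE = useSSE, useBMM = useBMM,
      useLocationMap = useLocationMap, useEdgeBranch = useEdgeBranch,
      denseUpward = denseUpward)
}

#' Optimizer and schedule configuration
#'
#' Defaults follow the reference protocol: SGD with momentum 0.9, weight
#' decay 0.0005, learning rate 0.001, batch size 8, 500 epochs. The "desk"
#' profile keeps the same optimizer but a short schedule for CPU-scale runs.
#'
#' @slot optimizer only "sgd"
#' @slot momentum,weightDecay,learningRate,batchSize,epochs,seed numerics
#' @slot profile "paper" or "desk"
#' @exportClass TrainConfig
setClass("TrainConfig", representation(
  optimizer = "character", momentum = "numeric", weightDecay = "numeric",
  learningRate = "numeric", batchSize = "integer", epochs = "integer",
  seed = "integer", profile = "character"
))

setValidity("TrainConfig", function(object) {
  msgs <- character()
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be > 0")
  if (object@batchSize < 1L) msgs <- c(msgs, "batchSize must be >= 1")
  if (object@epochs < 1L) msgs <- c(msgs, "epochs must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @rdname TrainConfig-class
#' @param optimizer,momentum,weightDecay,learningRate,batchSize,epochs see slots
#' @param seed,profile see slots
#' @export
trainConfig <- function(optimizer = "sgd", momentum = 0.9,
                        weightDecay = 5e-4, learningRate = 1e-3,
                        batchSize = 8L, epochs = 500L, seed = 1L,
                        profile = c("paper", "desk")) {
  profile <- match.arg(profile)
  new("TrainConfig", optimizer = optimizer, momentum = momentum,
      weightDecay = weightDecay, learningRate = learningRate,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed), profile = profile)
}

#' @rdname TrainConfig-class
#' @param ... overrides passed to [trainConfig()]
#' @export
deskTrainConfig <- function(...) {
  args <- list(...)
  defaults <- list(epochs = 10L, learningRate = 1e-4, profile = "desk")
  defaults[names(args)] <- args
  do.call(trainConfig, defaults)
}
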
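# Dataset augmentation, subject-level splitting, and the pixel-overlap
# evaluation metrics (Dice, precision, pixel accuracy).

rot90ccw <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]

#' Rotate a sample by a right angle
#'
#' Rotates the image and both labels identically, counter-clockwise, by 90,
#' 180 or 270 degrees; a pixel at 0-based (r, c) lands at (c, n-1-r) under a
#' single 90-degree rotation. The class label is preserved.
#'
#' @param sample an [ImageSample-class] with square rasters
#' @param angle one of 90, 180, 270
#' @return the rotated [ImageSample-class]
#' @export
rotateSample <- function(sample, angle) {
  if (!angle %in% c(90, 180, 270)) {
    stop("angle must be one of 90, 180, 270")
  }
  img <- sampleImage(sample)
  if (nrow(img) != ncol(img)) stop("rotateSample requires square rasters")
  k <- angle / 90
  rot <- function(m) {
    for (i in seq_len(k)) m <- rot90ccw(m)
    m
  }
  imageSample(rot(img), rot(normalLabel(sample)),
              rot(boundaryLabel(sample)), sampleClass(sample),
              paste0(sampleID(sample), "_rot", angle))
}

nearestResize <- function(m, outSize) {
  n <- nrow(m)
  idx <- pmin(pmax(floor((seq_len(outSize) - 0.5) * n / outSize) + 1L, 1L), n)
  m[idx, idx, drop = FALSE]
}

bilinearResizeMat <- function(m, outSize) {
  arr <- array(m, c(nrow(m), ncol(m), 1L, 1L))
  out <- bilinear_fwd_cpp(arr, as.integer(outSize), as.integer(outSize))
  matrix(out, outSize)
}

#' Outward scaling augmentation (zoom about the tumor centroid)
#'
#' Zooms by `1 + factor`: a window of side `round(n / (1 + factor))`,
#' centered on the tumor centroid (clamped to stay in-bounds), is resampled
#' back to the full raster size. The image is resampled bilinearly, labels
#' with nearest-neighbor, and the boundary label is regenerated from the
#' scaled normal label.
#'
#' @param sample an [ImageSample-class] containing at least one tumor pixel
#' @param factor outward scaling proportion (0.5 means a 1.5x zoom)
#' @param boundaryWidth rim width used to regenerate the boundary label
#' @return the zoomed [ImageSample-class]
#' @export
scaleOutward <- function(sample, factor = 0.5, boundaryWidth = 2L) {
  normal <- normalLabel(sample)
  if (!any(normal > 0)) {
    stop("scaleOutward is undefined for tumor-free samples")
  }
  n <- nrow(normal)
  side <- max(1L, as.integer(round(n / (1 + factor))))
  if (side >= n) return(sample)
  cen <- which(normal > 0, arr.ind = TRUE)
  cy <- round(mean(cen[, 1]))
  cx <- round(mean(cen[, 2]))
  r0 <- min(max(1L, cy - side %/% 2L), n - side + 1L)
  c0 <- min(max(1L, cx - side %/% 2L), n - side + 1L)
  rows <- r0:(r0 + side - 1L)
  cols <- c0:(c0 + side - 1L)
  img <- bilinearResizeMat(sampleImage(sample)[rows, cols], n)
  newNormal <- nearestResize(normal[rows, cols, drop = FALSE], n)
  newNormal <- matrix(as.integer(newNormal > 0), n)
  newBoundary <- boundaryFromMask(newNormal, boundaryWidth)
  imageSample(img, newNormal, newBoundary,
              if (any(newNormal > 0)) "present" else "absent",
              paste0(sampleID(sample), "_zoom"))
}

#' Standard training-set augmentation
#'
#' Returns the originals plus, per original, the three right-angle rotations
#' and one 50% outward scaling: exactly `5 * length(samples)` samples.
#'
#' @param samples list of tumor-containing [ImageSample-class] objects
#' @param scaleFactor outward scaling proportion
#' @return the augmented list
#' @export
augmentTrainingSet <- function(samples, scaleFactor = 0.5) {
  out <- vector("list", 5L * length(samples))
  k <- 0L
  for (s in samples) {
    out[[k + 1L]] <- s
    out[[k + 2L]] <- rotateSample(s, 90)
    out[[k + 3L]] <- rotateSample(s, 180)
    out[[k + 4L]] <- rotateSample(s, 270)
    out[[k + 5L]] <- scaleOutward(s, scaleFactor)
    k <- k + 5L
  }
  out
}

#' Split a dataset into train/test partitions or cross-validation folds
#'
#' With `foldCount == 1` returns a `list(train=, test=)` split at
#' `trainFraction`; otherwise returns a list of folds, each with `train`
#' and `test` elements. Splitting is subject-level by default (all images
#' of a subject stay together), deterministic for a fixed seed.
#'
#' @param samples non-empty list of [ImageSample-class]
#' @param plan a [SplitPlan-class]
#' @return a train/test list or a list of folds
#' @export
splitDataset <- function(samples, plan) {
  if (length(samples) == 0L) stop("dataset must be non-empty")
  validObject(plan)
  ids <- vapply(samples, sampleID, character(1))
  units <- if (plan@bySubject) subjectOf(ids) else ids
  uniq <- unique(units)
  perm <- withSeed(plan@seed, sample(uniq))
  if (plan@foldCount == 1L) {
    nTrain <- round(plan@trainFraction * length(uniq))
    trainUnits <- perm[seq_len(nTrain)]
    list(train = samples[units %in% trainUnits],
         test = samples[!units %in% trainUnits])
  } else {
    if (length(uniq) < plan@foldCount) {
      stop("fewer subjects (", length(uniq), ") than folds (",
           plan@foldCount, ")")
    }
    foldOf <- rep(seq_len(plan@foldCount), length.out = length(perm))
    lapply(seq_len(plan@foldCount), function(f) {
      testUnits <- perm[foldOf == f]
      list(train = samples[!units %in% testUnits],
           test = samples[units %in% testUnits])
    })
  }
}

#' Pixelwise confusion counts of a thresholded prediction
#'
#' @param pred probability matrix in \[0,1\]
#' @param truth binary 0/1 matrix of the same shape
#' @param threshold binarization threshold (prediction >= threshold is tumor)
#' @return a [ConfusionCounts-class]
#' @export
confusionCounts <- function(pred, truth, threshold = 0.5) {
  if (!identical(dim(pred), dim(truth)) &&
      length(pred) != length(truth)) {
    stop("pred and truth must share a shape")
  }
  if (min(pred) < 0 || max(pred) > 1) stop("pred must lie in [0,1]")
  if (!all(truth %in% c(0, 1))) stop("truth must be binary (0/1)")
  pb <- pred >= threshold
  tb <- truth > 0
  new("ConfusionCounts",
      tp = sum(pb & tb), fp = sum(pb & !tb),
      tn = sum(!pb & !tb), fn = sum(!pb & tb))
}

#' Overlap metrics from confusion counts
#'
#' `dsc(c) = 2 TP / (FP + 2 TP + FN)`, `precision(c) = TP / (TP + FP)`,
#' `pixelAccuracy(c) = (TP + TN) / (TP + TN + FP + FN)`. When both the
#' prediction and the truth are empty (zero denominator), `dsc` and
#' `precision` return the sentinel 1; `precision` returns 0 when nothing is
#' predicted but tumor pixels exist.
#'
#' @param c a [ConfusionCounts-class]
#' @return a proportion in \[0,1\]
#' @export
dsc <- function(c) {
  den <- c@fp + 2 * c@tp + c@fn
  if (den == 0) return(1)
  2 * c@tp / den
}

#' @rdname dsc
#' @export
precision <- function(c) {
  den <- c@tp + c@fp
  if (den == 0) return(if (c@fn == 0) 1 else 0)
  c@tp / den
}

#' @rdname dsc
#' @export
pixelAccuracy <- function(c) {
  den <- c@tp + c@tn + c@fp + c@fn
  if (den == 0) return(1)
  (c@tp + c@tn) / den
}

#' Split-and-augmentation dataset arithmetic
#'
#' Computes the image counts implied by a subject set, a train fraction and
#' a per-image augmentation multiplier:
#' `train = round(n p f) m`, `test = n p - round(n p f)`, and their sum.
#' With 215 subjects, 3 images each, an 80% training split and multiplier 5
#' (original + 3 rotations + 1 zoom) this gives 2580 training images, 129
#' test images and 2709 in total.
#'
#' @param nSubjects,perSubject positive integers
#' @param trainFraction proportion in (0,1)
#' @param augmentationMultiplier 1 + augmentations per training image
#' @return named numeric vector `c(train=, test=, total=)`
#' @export
datasetAccounting <- function(nSubjects, perSubject, trainFraction,
                              augmentationMultiplier) {
  total0 <- nSubjects * perSubject
  nTrain0 <- round(total0 * trainFraction)
  train <- nTrain0 * augmentationMultiplier
  test <- total0 - nTrain0
  c(train = train, test = test, total = train + test)
}

#' Write a per-sample metrics report as TSV and JSON
#'
#' @param report data frame with one row per sample (as returned by
#'   [evaluateSegmenter()])
#' @param dir output directory
#' @return invisibly, the aggregate list
#' @export
writeMetricsReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report, file.path(dir, "metrics_per_sample.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  agg <- list(
    n = nrow(report),
    dsc = list(mean = mean(report$dsc), sd = stats::sd(report$dsc)),
    precision = list(mean = mean(report$precision),
                     sd = stats::sd(report$precision)),
    accuracy = list(mean = mean(report$accuracy),
                    sd = stats::sd(report$accuracy))
  )
  jsonlite::write_json(agg, file.path(dir, "metrics_aggregate.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(agg)
}
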
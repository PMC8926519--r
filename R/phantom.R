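# Synthetic nonenhanced-MRI-like phantom generator. Emulates the regime the
# segmentation model targets: low tumor/background contrast, Gaussian-blurred
# tumor margins, tumor size diversity, and tumor-like background distractors
# over a smoothly textured background.

# run expr with a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# discrete filled ellipse with equivalent radius r, axis ratio rho, angle th
ellipseMask <- function(size, cy, cx, r, rho, th) {
  a <- r / sqrt(rho)
  b <- r * sqrt(rho)
  ii <- matrix(seq_len(size), size, size)
  jj <- matrix(seq_len(size), size, size, byrow = TRUE)
  di <- ii - cy
  dj <- jj - cx
  u <- di * cos(th) + dj * sin(th)
  v <- -di * sin(th) + dj * cos(th)
  m <- (u / a)^2 + (v / b)^2 <= 1
  matrix(as.integer(m), size)
}

#' Inner boundary of a binary mask
#'
#' Returns the mask pixels lying within `width` (4-neighborhood distance) of
#' the mask complement: the mask minus its erosion by a diamond structuring
#' element of radius `width`. The result is always a subset of the mask.
#'
#' @param mask binary (0/1) matrix
#' @param width rim width in pixels (>= 1)
#' @return a 0/1 integer matrix
#' @examples
#' m <- matrix(0L, 5, 5); m[2:4, 2:4] <- 1L
#' sum(boundaryFromMask(m, 1))  # the 8 perimeter pixels
#' @export
boundaryFromMask <- function(mask, width = 2L) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)")
  if (width < 1L) stop("width must be >= 1")
  m <- matrix(as.integer(mask), nrow(mask))
  if (!any(m == 1L)) return(m)
  brush <- EBImage::makeBrush(2L * as.integer(width) + 1L, shape = "diamond")
  eroded <- EBImage::erode(m, brush)
  out <- m
  out[eroded > 0] <- 0L
  matrix(as.integer(out), nrow(mask))
}

#' Fill a closed boundary rim to recover the full mask
#'
#' Fills the holes enclosed by a binary rim, returning the union of the rim
#' and its interior. Open curves enclose nothing and fill to themselves.
#' For a simply connected mask `m`, `fillBoundary(boundaryFromMask(m, w))`
#' recovers `m` for any rim width `w >= 1`.
#'
#' @param boundary binary (0/1) matrix
#' @return a 0/1 integer matrix
#' @export
fillBoundary <- function(boundary) {
  if (!all(boundary %in% c(0, 1))) stop("boundary must be binary (0/1)")
  m <- matrix(as.integer(boundary), nrow(boundary))
  if (!any(m == 1L)) return(m)
  filled <- EBImage::fillHull(m)
  matrix(as.integer(filled > 0), nrow(boundary))
}

# place n non-overlapping ellipses; returns list of parameter lists
placeEllipses <- function(n, size, radiusRange, existing = list(),
                          margin = 4, gap = 8) {
  out <- existing
  placed <- list()
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(500L)) {
      r <- stats::runif(1, radiusRange[1], radiusRange[2])
      rho <- stats::runif(1, 0.5, 1)
      th <- stats::runif(1, 0, pi)
      a <- r / sqrt(rho)
      lim <- a + margin
      if (2 * lim >= size) next
      cy <- stats::runif(1, lim, size - lim)
      cx <- stats::runif(1, lim, size - lim)
      clash <- FALSE
      for (e in out) {
        if (sqrt((cy - e$cy)^2 + (cx - e$cx)^2) < a + e$a + gap) {
          clash <- TRUE
          break
        }
      }
      if (!clash) {
        e <- list(cy = cy, cx = cx, r = r, rho = rho, th = th, a = a)
        out <- c(out, list(e))
        placed <- c(placed, list(e))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place ", n, " non-overlapping blobs; ",
           "tumorRadiusRange/nTumorsRange too crowded for imageSize")
    }
  }
  placed
}

#' Generate one synthetic phantom with consistent labels
#'
#' Draws `n` elliptical tumors (count from `nTumorsRange`) at intensity
#' offset `tumorContrast` over a smoothly textured background, blurs their
#' edges, adds disjoint lower-contrast distractor blobs and pixel noise,
#' and derives the whole-tumor ("normal") and rim ("boundary") labels.
#' Output is bit-identical for a fixed `(config, seed)` pair.
#'
#' @param config a [PhantomConfig-class]
#' @param seed integer seed for this sample (defaults to `config@seed`)
#' @param sampleID identifier stored in the sample
#' @param boundaryWidth rim width of the boundary label in pixels
#' @return an [ImageSample-class]
#' @examples
#' s <- makePhantom(phantomConfig(imageSize = 64, tumorRadiusRange = c(4, 10)),
#'                  seed = 1)
#' @export
makePhantom <- function(config, seed = config@seed, sampleID = "sample",
                        boundaryWidth = 2L) {
  validObject(config)
  size <- config@imageSize
  withSeed(seed, {
    # smooth organ-like background texture
    tex <- matrix(stats::runif(size * size), size)
    tex <- EBImage::gblur(tex, sigma = size / 16)
    tex <- tex - mean(tex)
    sdt <- stats::sd(as.vector(tex))
    if (sdt > 0) tex <- tex / sdt * 0.02
    bg <- 0.4 + tex

    nTum <- if (config@nTumorsRange[1] == config@nTumorsRange[2]) {
      config@nTumorsRange[1]
    } else {
      sample(seq(config@nTumorsRange[1], config@nTumorsRange[2]), 1)
    }
    tumors <- if (nTum > 0) {
      placeEllipses(nTum, size, config@tumorRadiusRange,
                    gap = 8 + 2 * config@edgeBlurSigma)
    } else list()
    normal <- matrix(0L, size, size)
    for (e in tumors) {
      normal <- pmax(normal, ellipseMask(size, e$cy, e$cx, e$r, e$rho, e$th))
    }

    nDis <- if (config@nDistractorsRange[1] == config@nDistractorsRange[2]) {
      config@nDistractorsRange[1]
    } else {
      sample(seq(config@nDistractorsRange[1], config@nDistractorsRange[2]), 1)
    }
    disRange <- c(config@tumorRadiusRange[1],
                  mean(config@tumorRadiusRange))
    dmask <- matrix(0L, size, size)
    if (nDis > 0) {
      dis <- tryCatch(
        placeEllipses(nDis, size, disRange, existing = tumors,
                      gap = 8 + 2 * config@edgeBlurSigma),
        error = function(e) list())
      for (e in dis) {
        dmask <- pmax(dmask, ellipseMask(size, e$cy, e$cx, e$r, e$rho, e$th))
      }
      dmask[normal > 0] <- 0L  # ground truth stays unambiguous
    }

    blurIf <- function(m) {
      if (config@edgeBlurSigma > 0) {
        EBImage::gblur(m + 0, sigma = config@edgeBlurSigma)
      } else m + 0
    }
    img <- bg + config@tumorContrast * blurIf(normal) +
      config@distractorContrast * blurIf(dmask)
    if (config@noiseSigma > 0) {
      img <- img + matrix(stats::rnorm(size * size, 0, config@noiseSigma),
                          size)
    }
    img <- pmin(pmax(img, 0), 1)

    boundary <- boundaryFromMask(normal, boundaryWidth)
    imageSample(img, normal, boundary,
                classLabel = if (any(normal > 0)) "present" else "absent",
                sampleID = sampleID)
  })
}

#' Generate a multi-subject phantom dataset
#'
#' Generates `perSubject` phantoms for each of `nSubjects` subjects; sample
#' identifiers are `S<subject>_I<image>` so subject-level splitting is
#' possible downstream.
#'
#' @param nSubjects,perSubject non-negative integers
#' @param config a [PhantomConfig-class]
#' @param seed integer base seed; each sample gets a distinct derived seed
#' @param firstSubject number assigned to the first subject (lets several
#'   generated cohorts share one id space)
#' @return a list of [ImageSample-class] objects
#' @export
makeDataset <- function(nSubjects, perSubject, config, seed = config@seed,
                        firstSubject = 1L) {
  stopifnot(nSubjects >= 0, perSubject >= 0)
  out <- vector("list", nSubjects * perSubject)
  k <- 0L
  for (s in seq_len(nSubjects)) {
    for (i in seq_len(perSubject)) {
      k <- k + 1L
      sid <- sprintf("S%04d_I%02d", s + firstSubject - 1L, i)
      out[[k]] <- makePhantom(config, seed = as.integer(seed) + k - 1L,
                              sampleID = sid)
    }
  }
  out
}

# subject identifier encoded in the sample id (prefix before "_")
subjectOf <- function(sampleID) sub("_.*$", "", sampleID)

#' Write a dataset to disk as PNG (and optionally NIfTI) with a manifest
#'
#' Images are written as 8-bit grayscale PNG, masks as 0/255 PNG, and a
#' tab-separated manifest records sample id, subject id, class label and
#' file paths.
#'
#' @param samples list of [ImageSample-class]
#' @param dir output directory (created if missing)
#' @param nifti also write each image as a single-slice NIfTI volume
#' @return the manifest data frame, invisibly
#' @export
writeDataset <- function(samples, dir, nifti = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    base <- file.path(dir, sampleID(s))
    png::writePNG(sampleImage(s), paste0(base, "_image.png"))
    png::writePNG(normalLabel(s) + 0, paste0(base, "_normal.png"))
    png::writePNG(boundaryLabel(s) + 0, paste0(base, "_boundary.png"))
    if (nifti) {
      RNifti::writeNifti(array(sampleImage(s), c(dim(sampleImage(s)), 1L)),
                         paste0(base, "_image.nii.gz"))
    }
    data.frame(sample_id = sampleID(s), subject_id = subjectOf(sampleID(s)),
               class_label = sampleClass(s),
               image = paste0(base, "_image.png"),
               normal_label = paste0(base, "_normal.png"),
               boundary_label = paste0(base, "_boundary.png"),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
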
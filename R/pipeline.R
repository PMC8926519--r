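# Two-stage training pipeline: (1) train the localization network (coarse
# U-Net + classifier) and freeze its class-activation location maps;
# (2) train the dual-branch segmentation network guided by those maps.
# Plus evaluation, cross-validation, checkpoints and config I/O.

stackBatch <- function(samples, what = c("image", "normal", "boundary")) {
  what <- match.arg(what)
  n <- length(samples)
  d <- dim(sampleImage(samples[[1]]))
  arr <- array(0, c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) {
    arr[, , 1L, i] <- switch(what,
      image = sampleImage(samples[[i]]),
      normal = normalLabel(samples[[i]]),
      boundary = boundaryLabel(samples[[i]]))
  }
  arr
}

stackMaps <- function(maps, ids, d) {
  arr <- array(0, c(d[1], d[2], 1L, length(ids)))
  for (i in seq_along(ids)) arr[, , 1L, i] <- maps[[ids[i]]]
  arr
}

batchIndices <- function(n, batchSize) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batchSize))
}

#' Train the localization network
#'
#' Stage one of the pipeline. The coarse U-Net is optimized with the
#' localization loss (Dice + weighted hard-pixel rank loss) on the
#' whole-tumor labels; the classifier is then trained with cross-entropy on
#' the image-level labels, taking the image stacked with the (frozen)
#' coarse mask as its 2-channel input.
#'
#' @param samples training [ImageSample-class] list containing both
#'   tumor-present and tumor-absent images
#' @param netConfig a [NetworkConfig-class]
#' @param config a [TrainConfig-class]
#' @param locCfg a [LocLossConfig-class]
#' @param clfLearningRate learning rate for the classifier stage (the
#'   overlap-driven U-Net loss and the mean cross-entropy have very
#'   different gradient scales; defaults to `config@learningRate`)
#' @param clfEpochs classifier epochs (defaults to `config@epochs`)
#' @param verbose print per-epoch losses
#' @return a localizer checkpoint (list with the two module states, the
#'   configs and the per-epoch loss log)
#' @export
trainLocalizer <- function(samples, netConfig = networkConfig(),
                           config = trainConfig(), locCfg = locLossConfig(),
                           clfLearningRate = NULL, clfEpochs = NULL,
                           verbose = FALSE) {
  if (is.null(clfLearningRate)) clfLearningRate <- config@learningRate
  if (is.null(clfEpochs)) clfEpochs <- config@epochs
  classes <- vapply(samples, sampleClass, character(1))
  if (length(unique(classes)) < 2L) {
    stop("localizer training needs both tumor-present and tumor-absent samples")
  }
  validObject(config)
  unet <- coarseUNet(netConfig, seed = config@seed)
  clf <- camClassifier(netConfig, seed = config@seed + 1L)
  log <- NULL
  withSeed(config@seed + 2L, {
    params <- moduleParams(unet)
    state <- list()
    segLossLog <- numeric(config@epochs)
    for (ep in seq_len(config@epochs)) {
      ls <- c()
      for (bi in batchIndices(length(samples), config@batchSize)) {
        x <- agConst(stackBatch(samples[bi], "image"))
        beta <- stackBatch(samples[bi], "normal")
        alpha <- coarseFwd(unet, x, train = TRUE)
        loss <- agScalarComb(
          list(agDiceLoss(alpha, beta, locCfg@smooth),
               agRankLossNode(alpha, beta, locCfg@K, locCfg@mu)),
          c(1, locCfg@lambda1))
        agZeroGrad(params)
        agBackward(loss)
        state <- sgdStep(params, state, config@learningRate,
                         config@momentum, config@weightDecay)
        ls <- c(ls, loss$val)
      }
      segLossLog[ep] <- mean(ls)
      if (verbose) message(sprintf("localizer epoch %d: loc loss %.4f",
                                   ep, segLossLog[ep]))
    }

    # freeze normalization statistics from training batches, then compute
    # the frozen coarse masks that feed the classifier
    bnRecalibrate(unet, {
      for (idx in utils::head(chunkSeq(length(samples), config@batchSize), 10L)) {
        agNoGrad(coarseFwd(unet, agConst(stackBatch(samples[idx], "image")),
                           train = TRUE))
      }
    })
    masks <- coarseSegmentMany(unet, lapply(samples, sampleImage))
    labels <- classIndex(classes)
    cparams <- moduleParams(clf)
    cstate <- list()
    clfLossLog <- numeric(clfEpochs)
    d <- dim(sampleImage(samples[[1]]))
    for (ep in seq_len(clfEpochs)) {
      ls <- c()
      for (bi in batchIndices(length(samples), config@batchSize)) {
        x <- array(0, c(d[1], d[2], 2L, length(bi)))
        for (i in seq_along(bi)) {
          x[, , 1L, i] <- sampleImage(samples[[bi[i]]])
          x[, , 2L, i] <- masks[[bi[i]]]
        }
        out <- classifierFwd(clf, agConst(x), train = TRUE)
        loss <- agSoftmaxCE(out$logits, labels[bi])
        agZeroGrad(cparams)
        agBackward(loss)
        cstate <- sgdStep(cparams, cstate, clfLearningRate,
                          config@momentum, config@weightDecay)
        ls <- c(ls, loss$val)
      }
      clfLossLog[ep] <- mean(ls)
      if (verbose) message(sprintf("classifier epoch %d: CE %.4f",
                                   ep, clfLossLog[ep]))
    }
    bnRecalibrate(clf, {
      for (idx in utils::head(chunkSeq(length(samples), config@batchSize), 10L)) {
        x <- array(0, c(d[1], d[2], 2L, length(idx)))
        for (i in seq_along(idx)) {
          x[, , 1L, i] <- sampleImage(samples[[idx[i]]])
          x[, , 2L, i] <- masks[[idx[i]]]
        }
        agNoGrad(classifierFwd(clf, agConst(x), train = TRUE))
      }
    })
    log <- list(
      unet = data.frame(epoch = seq_len(config@epochs),
                        loc_loss = segLossLog),
      classifier = data.frame(epoch = seq_len(clfEpochs),
                              clf_loss = clfLossLog))
  })
  list(kind = "localizer", netConfig = netConfig, trainConfig = config,
       locCfg = locCfg, unet = moduleState(unet), clf = moduleState(clf),
       log = log)
}

localizerNets <- function(ckpt) {
  stopifnot(identical(ckpt$kind, "localizer"))
  unet <- coarseUNet(ckpt$netConfig, seed = 1L)
  loadModuleState(unet, ckpt$unet)
  clf <- camClassifier(ckpt$netConfig, seed = 1L)
  loadModuleState(clf, ckpt$clf)
  list(unet = unet, clf = clf)
}

#' Compute and cache location maps for a set of samples
#'
#' Runs the trained localizer on every sample: the coarse mask and image go
#' through the classifier, and the tumor-present class activation map
#' (min-max normalized) becomes the sample's location map. Samples whose
#' class label is "absent" get an all-zero map.
#'
#' @param ckpt a localizer checkpoint from [trainLocalizer()], or a path to
#'   one saved with [saveCheckpoint()]
#' @param samples list of [ImageSample-class]
#' @return named list of location-map matrices keyed by sample id
#' @export
makeLocationMaps <- function(ckpt, samples) {
  if (is.character(ckpt)) {
    if (!file.exists(ckpt)) stop("checkpoint file not found: ", ckpt)
    ckpt <- loadCheckpoint(ckpt)
  }
  nets <- localizerNets(ckpt)
  present <- vapply(samples, function(s) sampleClass(s) == "present",
                    logical(1))
  maps <- lapply(samples, function(s) {
    matrix(0, nrow(sampleImage(s)), ncol(sampleImage(s)))
  })
  if (any(present)) {
    imgs <- lapply(samples[present], sampleImage)
    coarse <- coarseSegmentMany(nets$unet, imgs)
    cams <- classifyAndCamMany(nets$clf, imgs, coarse)
    maps[present] <- lapply(cams, `[[`, "locationMap")
  }
  names(maps) <- vapply(samples, sampleID, character(1))
  maps
}

#' Write cached location maps to disk as 32-bit float NIfTI volumes
#'
#' @param maps named list from [makeLocationMaps()]
#' @param dir output directory
#' @return invisibly, the written paths
#' @export
writeLocationMaps <- function(maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(maps), function(id) {
    path <- file.path(dir, paste0(id, "_locmap.nii.gz"))
    RNifti::writeNifti(array(maps[[id]], c(dim(maps[[id]]), 1L)), path,
                       datatype = "float")
    path
  }, character(1))
  invisible(paths)
}

#' Train the dual-branch segmentation network
#'
#' Stage two of the pipeline: optimizes the four-part segmentation loss
#' (area BCE+Dice, edge BCE, detector BCE, weighted branch-consistency
#' divergence) with SGD, guided by the frozen location maps.
#'
#' @param samples training [ImageSample-class] list (tumor-present)
#' @param maps named location-map list covering every training sample
#' @param netConfig a [NetworkConfig-class]
#' @param config a [TrainConfig-class]
#' @param segCfg a [SegLossConfig-class]
#' @param verbose print per-epoch losses
#' @return a segmenter checkpoint (module state + configs + per-term log)
#' @export
trainSegmenter <- function(samples, maps, netConfig = networkConfig(),
                           config = trainConfig(), segCfg = segLossConfig(),
                           verbose = FALSE) {
  ids <- vapply(samples, sampleID, character(1))
  missing <- setdiff(ids, names(maps))
  if (length(missing)) {
    stop("location maps missing for samples: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ..." else "")
  }
  validObject(config)
  net <- dualSegNet(netConfig, seed = config@seed)
  useEdge <- netConfig@useEdgeBranch
  log <- NULL
  withSeed(config@seed + 3L, {
    params <- moduleParams(net)
    state <- list()
    logRows <- vector("list", config@epochs)
    d <- dim(sampleImage(samples[[1]]))
    for (ep in seq_len(config@epochs)) {
      terms <- c(area = 0, edge = 0, ed = 0, con = 0, total = 0)
      nb <- 0L
      for (bi in batchIndices(length(samples), config@batchSize)) {
        x <- agConst(stackBatch(samples[bi], "image"))
        M <- agConst(stackMaps(maps, ids[bi], d))
        normal <- stackBatch(samples[bi], "normal")
        boundary <- stackBatch(samples[bi], "boundary")
        out <- dualSegFwd(net, x, M, train = TRUE)
        area <- agScalarComb(list(
          agBCELoss(out$alpha, normal, segCfg@clampEps, segCfg@positiveOnly),
          agDiceLoss(out$alpha, normal, segCfg@smooth)))
        ed <- agBCELoss(out$q, boundary, segCfg@clampEps, segCfg@positiveOnly)
        if (useEdge) {
          edge <- agBCELoss(out$p, boundary, segCfg@clampEps,
                            segCfg@positiveOnly)
          con <- agConLossNode(out$p, out$q, segCfg@clampEps)
          total <- agScalarComb(list(area, edge, ed, con),
                                c(1, 1, 1, segCfg@lambda2))
        } else {
          edge <- NULL; con <- NULL
          total <- agScalarComb(list(area, ed))
        }
        agZeroGrad(params)
        agBackward(total)
        state <- sgdStep(params, state, config@learningRate,
                         config@momentum, config@weightDecay)
        terms <- terms + c(area$val,
                           if (useEdge) edge$val else 0,
                           ed$val,
                           if (useEdge) con$val else 0,
                           total$val)
        nb <- nb + 1L
      }
      terms <- terms / nb
      logRows[[ep]] <- data.frame(epoch = ep, L_area = terms[1],
                                  L_edge = terms[2], L_ed = terms[3],
                                  L_con = terms[4], total = terms[5])
      if (verbose) message(sprintf("segmenter epoch %d: total %.4f",
                                   ep, terms[5]))
    }
    bnRecalibrate(net, {
      for (idx in utils::head(chunkSeq(length(samples), config@batchSize), 10L)) {
        agNoGrad(dualSegFwd(net, agConst(stackBatch(samples[idx], "image")),
                            agConst(stackMaps(maps, ids[idx], d)),
                            train = TRUE))
      }
    })
    log <- do.call(rbind, logRows)
  })
  list(kind = "segmenter", netConfig = netConfig, trainConfig = config,
       segCfg = segCfg, net = moduleState(net), log = log)
}

segmenterNet <- function(ckpt) {
  stopifnot(identical(ckpt$kind, "segmenter"))
  net <- dualSegNet(ckpt$netConfig, seed = 1L)
  loadModuleState(net, ckpt$net)
  net
}

#' Evaluate a trained segmenter on held-out samples
#'
#' Computes per-sample Dice, precision and pixel accuracy of the
#' thresholded area prediction against the whole-tumor label, plus the
#' aggregate mean and standard deviation.
#'
#' @param ckpt a segmenter checkpoint from [trainSegmenter()] (or a
#'   [dualSegNet()] network)
#' @param maps named location-map list covering the test samples
#' @param samples non-empty test [ImageSample-class] list
#' @param threshold binarization threshold for the area map
#' @return data frame with one row per sample and an `aggregate` attribute
#'   (list of mean/sd per metric)
#' @export
evaluateSegmenter <- function(ckpt, maps, samples, threshold = 0.5) {
  if (length(samples) == 0L) stop("test set must be non-empty")
  net <- if (inherits(ckpt, "agModule")) ckpt else segmenterNet(ckpt)
  ids <- vapply(samples, sampleID, character(1))
  missing <- setdiff(ids, names(maps))
  if (length(missing)) {
    stop("location maps missing for samples: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  triples <- segmentForwardMany(net, lapply(samples, sampleImage),
                                lapply(ids, function(id) maps[[id]]))
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    cc <- confusionCounts(areaMap(triples[[i]]), normalLabel(s), threshold)
    data.frame(sample_id = sampleID(s), dsc = dsc(cc),
               precision = precision(cc), accuracy = pixelAccuracy(cc),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  attr(report, "aggregate") <- list(
    dsc = c(mean = mean(report$dsc), sd = stats::sd(report$dsc)),
    precision = c(mean = mean(report$precision), sd = stats::sd(report$precision)),
    accuracy = c(mean = mean(report$accuracy), sd = stats::sd(report$accuracy)))
  report
}

#' Run the full two-stage pipeline on one train/test split
#'
#' Trains the localizer on all training samples, freezes the location maps,
#' trains the segmenter on the tumor-present training samples, and
#' evaluates on the test samples.
#'
#' @param train,test [ImageSample-class] lists; `train` must contain both
#'   classes
#' @param netConfig,config,locCfg,segCfg configuration objects
#' @param locTrainConfig optimizer settings for the localizer stage (the
#'   overlap-driven localization loss supports a larger step size than the
#'   pixel-summed segmentation loss; defaults to `config`)
#' @param clfLearningRate,clfEpochs classifier overrides, see
#'   [trainLocalizer()]
#' @param augment apply the 5x rotation/zoom augmentation to the
#'   tumor-present training samples
#' @param verbose print progress
#' @return list with the two checkpoints, the map caches and the
#'   evaluation report
#' @export
runPipeline <- function(train, test, netConfig = networkConfig(),
                        config = trainConfig(), locCfg = locLossConfig(),
                        segCfg = segLossConfig(), locTrainConfig = config,
                        clfLearningRate = NULL, clfEpochs = NULL,
                        augment = FALSE, verbose = FALSE) {
  loc <- trainLocalizer(train, netConfig, locTrainConfig, locCfg,
                        clfLearningRate = clfLearningRate,
                        clfEpochs = clfEpochs, verbose = verbose)
  segTrain <- Filter(function(s) sampleClass(s) == "present", train)
  if (augment) segTrain <- augmentTrainingSet(segTrain)
  trainMaps <- makeLocationMaps(loc, segTrain)
  seg <- trainSegmenter(segTrain, trainMaps, netConfig, config, segCfg,
                        verbose = verbose)
  testMaps <- makeLocationMaps(loc, test)
  report <- evaluateSegmenter(seg, testMaps, test)
  list(localizer = loc, segmenter = seg, trainMaps = trainMaps,
       testMaps = testMaps, report = report)
}

#' Subject-disjoint k-fold cross-validation of the full pipeline
#'
#' @param samples full dataset (both classes)
#' @param folds number of folds (subjects >= folds required)
#' @param netConfig,config,locCfg,segCfg configuration objects
#' @param augment,verbose as in [runPipeline()]
#' @return list of per-fold results plus a `summary` element with the mean
#'   and standard deviation of the fold means
#' @export
crossValidate <- function(samples, folds, netConfig = networkConfig(),
                          config = trainConfig(), locCfg = locLossConfig(),
                          segCfg = segLossConfig(), locTrainConfig = config,
                          clfLearningRate = NULL, clfEpochs = NULL,
                          augment = FALSE, verbose = FALSE) {
  plan <- splitPlan(trainFraction = 1 - 1 / folds, foldCount = folds,
                    seed = config@seed)
  foldSplits <- splitDataset(samples, plan)
  results <- lapply(seq_along(foldSplits), function(f) {
    if (verbose) message("fold ", f, "/", length(foldSplits))
    sp <- foldSplits[[f]]
    runPipeline(sp$train, sp$test, netConfig, config, locCfg, segCfg,
                locTrainConfig = locTrainConfig,
                clfLearningRate = clfLearningRate, clfEpochs = clfEpochs,
                augment = augment, verbose = verbose)
  })
  foldMeans <- vapply(results, function(r) {
    a <- attr(r$report, "aggregate")
    c(dsc = unname(a$dsc["mean"]), precision = unname(a$precision["mean"]),
      accuracy = unname(a$accuracy["mean"]))
  }, numeric(3))
  summary <- list(mean = rowMeans(foldMeans),
                  sd = apply(foldMeans, 1, stats::sd),
                  foldMeans = foldMeans)
  list(folds = results, summary = summary)
}

## ---- checkpoints and configuration files ------------------------------

#' Save or load a checkpoint
#'
#' Checkpoints bundle configuration, parameter arrays, normalization
#' statistics and the training log; a loaded checkpoint reproduces the
#' saved network's predictions exactly.
#'
#' @param ckpt checkpoint list from [trainLocalizer()] or [trainSegmenter()]
#' @param path file path
#' @return [loadCheckpoint()] returns the checkpoint list
#' @export
saveCheckpoint <- function(ckpt, path) {
  stopifnot(ckpt$kind %in% c("localizer", "segmenter"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!is.list(ckpt) || !ckpt$kind %in% c("localizer", "segmenter")) {
    stop("not a valid checkpoint: ", path)
  }
  ckpt
}

#' Read an experiment configuration from a flat YAML file
#'
#' Keys mirror the constructor arguments of [phantomConfig()],
#' [networkConfig()] and [trainConfig()], grouped under `phantom`,
#' `network` and `train`; missing keys keep their defaults.
#'
#' @param path YAML file path
#' @return list with `phantom`, `network`, `train` configuration objects
#' @export
readExperimentConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(fun, vals) do.call(fun, as.list(vals %||% list()))
  list(phantom = build(phantomConfig, raw$phantom),
       network = build(networkConfig, raw$network),
       train = build(trainConfig, raw$train))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a per-epoch training log as TSV
#'
#' @param log data frame (checkpoint `$log`)
#' @param path output file
#' @export
writeTrainingLog <- function(log, path) {
  utils::write.table(log, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
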
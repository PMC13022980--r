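## End-to-end orchestration: generate -> preprocess -> (optional search) ->
## 5-fold cross-validated head training -> metrics report. One global seed
## is fanned out to per-stage child seeds so stages are individually
## reproducible; every artifact records its seed.

#' Largest-remainder class counts
#'
#' Scales a class-probability vector to exact integer counts summing to n
#' (floors plus largest fractional remainders), e.g. the EyePACS
#' composition scaled to a desk-size dataset.
#'
#' @param n total count.
#' @param probs class probabilities (default the EyePACS composition).
#' @return integer vector of counts summing to n.
#' @export
scaledClassCounts <- function(n, probs = eyepacsClassProbs()) {
  raw <- probs / sum(probs) * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Default end-to-end run configuration
#'
#' Returns the default [runEndToEnd()] configuration as a named list;
#' override any field by passing a partial list to `runEndToEnd()`.
#'
#' @return named list of defaults.
#' @export
defaultRunConfig <- function() {
  list(nImages = 500, classCounts = NULL, imageSize = 224, seed = 1,
       clahe = TRUE, claheClip = 2, claheGrid = c(8, 8),
       folds = 5, valFraction = 0.1,
       epochs = 3, batchSize = 16, lr = 1e-3, weightDecay = 1e-5,
       backbone = list(widthMultiplier = 0.5, depthwiseKernel = 3,
                       embedDim = 128, nHeads = 4, attentionDropout = 0),
       search = FALSE, searchEpochs = 2, searchPopulation = 6,
       searchIterations = 10, searchImageSize = 112, searchImages = 60,
       augmentTraining = FALSE, augmentRounds = 1, chunkSize = 16)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; fields override [defaultRunConfig()].
#' @return configuration list.
#' @export
runConfigFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  cfg[names(y)] <- y
  cfg
}

#' Run the full severity-grading pipeline
#'
#' Generates a synthetic graded dataset, preprocesses it (CLAHE on the
#' luminance channel, then \[-1,1\] normalization), optionally runs the
#' IWO hyperparameter search on a small side dataset, extracts backbone
#' features, trains the cKAN head under stratified k-fold cross-validation
#' (augmentation, when enabled, touches training folds only -- the harness
#' asserts that no test-fold sample is ever seen augmented), evaluates
#' each fold's untouched test split and writes a metrics report. Every
#' stage logs its seed; rerunning with the same seed reproduces the
#' metric table exactly.
#'
#' @param config partial configuration list (see [defaultRunConfig()]).
#' @param outDir optional output directory (created if missing) for the
#'   manifest, per-fold metrics/confusions, summary JSON and log file.
#' @param verbose log progress to the console.
#' @return a report list: `summary` (fold-aggregated accuracy/macro
#'   metrics with SD and CI half-width), `perFold`, `confusions`, `scores`
#'   (pooled out-of-fold class probabilities), `manifest`,
#'   `foldAssignment`, `search` (when run), `config`.
#' @export
runEndToEnd <- function(config = list(), outDir = NULL, verbose = TRUE) {
  cfg <- defaultRunConfig()
  cfg[names(config)] <- config
  logFile <- NULL
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    logFile <- file.path(outDir, "run.log")
  }
  say <- function(...) stageLog(sprintf(...), logFile, verbose)
  seed <- cfg$seed
  stageSeed <- function(i) childSeed(seed, 1000 + i)

  ## stage 1: generate
  counts <- cfg$classCounts %||% scaledClassCounts(cfg$nImages)
  say("generate: %d images (%s per class), size %d, seed %d",
      sum(counts), paste(counts, collapse = "/"), cfg$imageSize, stageSeed(1))
  ds <- generateFundusDataset(datasetSpec(classCounts = counts,
                                          imageSize = cfg$imageSize,
                                          seed = stageSeed(1)))
  labels <- ds$manifest$grade
  n <- length(labels)

  ## stage 2: preprocess
  say("preprocess: CLAHE=%s, normalize to [-1,1]", cfg$clahe)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    img <- ds$images[[i]]
    if (cfg$clahe) img <- claheEnhance(img, cfg$claheClip, cfg$claheGrid)
    images[[i]] <- normalizeSignedRange(img)
  }
  ds$images <- NULL

  ## stage 3: folds
  say("folds: stratified %d-fold, val fraction %.2f, seed %d",
      cfg$folds, cfg$valFraction, stageSeed(3))
  fa <- stratifiedKFold(labels, cfg$folds, cfg$valFraction,
                        seed = stageSeed(3))

  ## stage 4: optional hyperparameter search on a small side dataset
  searchOut <- NULL
  backboneCfg <- do.call(backboneConfig,
                         c(cfg$backbone, list(inputSize = cfg$imageSize)))
  if (isTRUE(cfg$search)) {
    say("search: IWO P=%d tmax=%d on %d side images at %d px",
        cfg$searchPopulation, cfg$searchIterations, cfg$searchImages,
        cfg$searchImageSize)
    sdata <- makeSearchData(cfg$searchImages, cfg$searchImageSize,
                            seed = stageSeed(4))
    searchOut <- runSearch(sdata,
                           iwoCfg = iwoConfig(populationSize = cfg$searchPopulation,
                                              tMax = cfg$searchIterations,
                                              seed = stageSeed(4)),
                           epochs = cfg$searchEpochs,
                           outDir = outDir)
    bb <- searchOut$champion$backbone
    backboneCfg <- backboneConfig(bb@widthMultiplier, bb@depthwiseKernel,
                                  bb@embedDim, bb@nHeads,
                                  bb@attentionDropout, cfg$imageSize)
    cfg$lr <- searchOut$champion$learningRate
    cfg$weightDecay <- searchOut$champion$weightDecay
    cfg$batchSize <- searchOut$champion$batchSize
    say("search champion: wm=%.2f k=%d d=%d h=%d lr=%.2e",
        bb@widthMultiplier, bb@depthwiseKernel, bb@embedDim, bb@nHeads,
        cfg$lr)
  }

  ## stage 5: backbone features (fixed random weights, shared across folds)
  say("features: backbone wm=%.2f k=%d embed=%d heads=%d, seed %d",
      backboneCfg@widthMultiplier, backboneCfg@depthwiseKernel,
      backboneCfg@embedDim, backboneCfg@nHeads, stageSeed(5))
  bw <- initBackboneWeights(backboneCfg, seed = stageSeed(5))
  features <- extractFeatures(images, bw, chunkSize = cfg$chunkSize)@data
  if (!isTRUE(cfg$augmentTraining)) images <- NULL

  ## stage 6: per-fold head training + evaluation
  headCfg <- ckanConfig()
  perFold <- list(); confusions <- list(); scores <- list()
  for (f in seq_len(cfg$folds)) {
    fd <- fa@folds[[f]]
    trIdx <- fd$train
    trFeat <- features[trIdx, , , , drop = FALSE]
    trLab <- labels[trIdx]
    if (isTRUE(cfg$augmentTraining)) {
      augIds <- character(0)
      augList <- list()
      for (r in seq_len(cfg$augmentRounds)) {
        for (i in trIdx) {
          augList[[length(augList) + 1]] <-
            augmentImage(images[[i]],
                         seed = childSeed(stageSeed(6), f * 100000 + r * 10000 + i))
          augIds <- c(augIds, images[[i]]@id)
        }
      }
      testIds <- ds$manifest$id[fd$test]
      if (length(intersect(augIds, testIds)))
        stop("augmentation leak: test-fold sample found in augmented batch")
      augFeat <- extractFeatures(augList, bw, chunkSize = cfg$chunkSize)@data
      trFeat <- abind4(trFeat, augFeat)
      trLab <- c(trLab, vapply(augList, grade, integer(1)))
    }
    say("fold %d: train %d (+%d aug) / val %d / test %d, %d epochs",
        f, length(fd$train),
        if (isTRUE(cfg$augmentTraining)) length(trLab) - length(fd$train) else 0L,
        length(fd$val), length(fd$test), cfg$epochs)
    tr <- trainHead(trFeat, trLab, headCfg, epochs = cfg$epochs,
                    batchSize = cfg$batchSize, lr = cfg$lr,
                    weightDecay = cfg$weightDecay,
                    valFeatures = features[fd$val, , , , drop = FALSE],
                    valLabels = labels[fd$val], patience = cfg$epochs,
                    seed = childSeed(stageSeed(6), f))
    testProbs <- predictHead(features[fd$test, , , , drop = FALSE], headCfg,
                             tr$params, "prob")
    pred <- max.col(testProbs, ties.method = "first") - 1L
    scores[[f]] <- data.frame(fold = f, index = fd$test,
                              label = labels[fd$test], testProbs)
    cm <- confusionCounts(labels[fd$test], pred, headCfg@nClasses)
    mm <- multiclassMetrics(cm)
    stopifnot(abs(mm$accuracy - sum(diag(cm)) / sum(cm)) < 1e-12)
    confusions[[f]] <- cm
    perFold[[f]] <- data.frame(fold = f, accuracy = mm$accuracy,
                               macroPrecision = mm$macro["precision"],
                               macroRecall = mm$macro["recall"],
                               macroF1 = mm$macro["f1"],
                               macroMcc = mm$macro["mcc"],
                               kappa = mm$kappa, row.names = NULL)
    say("fold %d: accuracy %.4f, kappa %.4f", f, mm$accuracy, mm$kappa)
  }
  foldTab <- do.call(rbind, perFold)

  summary <- lapply(names(foldTab)[-1], function(mname)
    foldSummary(foldTab[[mname]]))
  names(summary) <- names(foldTab)[-1]
  say("summary: accuracy %.4f +/- %.4f (95%% CI half-width)",
      summary$accuracy["mean"], summary$accuracy["ciHalfWidth"])

  report <- list(summary = summary, perFold = foldTab,
                 confusions = confusions, scores = do.call(rbind, scores),
                 manifest = ds$manifest,
                 foldAssignment = fa, search = searchOut, config = cfg,
                 seed = seed)
  if (!is.null(outDir)) {
    write.csv(ds$manifest, file.path(outDir, "manifest.csv"),
              row.names = FALSE)
    write.csv(foldTab, file.path(outDir, "fold_metrics.csv"),
              row.names = FALSE)
    for (f in seq_along(confusions))
      write.csv(confusions[[f]],
                file.path(outDir, sprintf("confusion_fold%d.csv", f)))
    jsonlite::write_json(
      list(seed = seed,
           summary = lapply(summary, as.list),
           config = cfg[c("nImages", "imageSize", "folds", "epochs",
                          "batchSize", "lr", "weightDecay", "clahe",
                          "search")]),
      file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
    say("artifacts written to %s", outDir)
  }
  report
}

## Concatenate two rank-4 arrays along the batch axis.
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[-1] == db[-1]))
  out <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

#' Build a small search dataset
#'
#' Balanced synthetic train/validation splits at a reduced image size for
#' candidate evaluation during the hyperparameter search (the backbone is
#' input-size agnostic; the head sees the same channel layout).
#'
#' @param nImages total images (2/3 train, 1/3 validation).
#' @param imageSize image side in pixels (multiple of 16).
#' @param seed integer seed.
#' @return list(trainImages, trainLabels, valImages, valLabels) with
#'   images as \[-1,1\] arrays.
#' @export
makeSearchData <- function(nImages = 90, imageSize = 112, seed = 1) {
  per <- nImages %/% 5
  counts <- rep(per, 5)
  counts[1] <- counts[1] + nImages - sum(counts)
  ds <- generateFundusDataset(datasetSpec(classCounts = counts,
                                          imageSize = imageSize,
                                          seed = seed))
  n <- length(ds$images)
  arr <- array(0, c(n, imageSize, imageSize, 3))
  for (i in seq_len(n))
    arr[i, , , ] <- 2 * ds$images[[i]]@pixels - 1
  labels <- ds$manifest$grade
  idx <- withSeed(childSeed(seed, 2), sample(n))
  nTr <- round(2 * n / 3)
  tr <- idx[seq_len(nTr)]; va <- idx[(nTr + 1):n]
  list(trainImages = arr[tr, , , , drop = FALSE], trainLabels = labels[tr],
       valImages = arr[va, , , , drop = FALSE], valLabels = labels[va])
}
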
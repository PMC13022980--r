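## Hyperparameter search: encodes the backbone + training search space,
## evaluates a candidate by short head training on synthetic data, and
## scores it with the composite accuracy/loss/FLOPs fitness.

#' The backbone + training hyperparameter search space
#'
#' Eight dimensions: learning rate (log, \[1e-5, 1e-2\]), weight decay
#' (log, \[1e-6, 1e-3\]), batch size (menu 16/32), ShuffleNet width
#' multiplier (menu 0.5/0.75/1.0), depthwise kernel (menu 3/5), attention
#' embedding dimension (menu 128/256/384), attention heads (menu 4/8) and
#' attention dropout (continuous \[0, 0.3\]). Categorical dimensions are
#' optimized on a continuous relaxation \[0, menu size) and decoded by
#' floor. The published batch-size menu prints "16, 23"; 23 is treated as
#' a typo for 32.
#'
#' @return a [SearchSpace-class].
#' @export
hyperSearchSpace <- function() {
  searchSpace(
    lower = c(log10(1e-5), log10(1e-6), 0, 0, 0, 0, 0, 0),
    upper = c(log10(1e-2), log10(1e-3), 0, 0, 0, 0, 0, 0.3),
    kind = c("log", "log", "categorical", "categorical", "categorical",
             "categorical", "categorical", "continuous"),
    menus = list(NULL, NULL, c(16, 32), c(0.5, 0.75, 1.0), c(3, 5),
                 c(128, 256, 384), c(4, 8), NULL),
    dimNames = c("learningRate", "weightDecay", "batchSize",
                 "widthMultiplier", "depthwiseKernel", "embedDim", "nHeads",
                 "attentionDropout"))
}

#' Decode a search-space position
#'
#' Log dimensions are exponentiated; categorical dimensions are decoded by
#' flooring the continuous relaxation into the menu (the upper bound maps
#' to the last item).
#'
#' @param position numeric vector in the space's bounds.
#' @param space a [SearchSpace-class].
#' @param inputSize input image side for the backbone config.
#' @return a named list of decoded values plus `backbone`, a
#'   [BackboneConfig-class].
#' @export
decodePosition <- function(position, space = hyperSearchSpace(),
                           inputSize = 224) {
  d <- spaceDim(space)
  stopifnot(length(position) == d)
  vals <- vector("list", d)
  names(vals) <- space@dimNames
  for (j in seq_len(d)) {
    vals[[j]] <- switch(space@kind[j],
      continuous = position[j],
      log = 10^position[j],
      categorical = {
        menu <- space@menus[[j]]
        k <- min(length(menu), floor(position[j]) + 1)
        menu[max(1, k)]
      })
  }
  if (all(c("widthMultiplier", "depthwiseKernel", "embedDim", "nHeads",
            "attentionDropout") %in% names(vals)))
    vals$backbone <- backboneConfig(vals$widthMultiplier, vals$depthwiseKernel,
                                    vals$embedDim, vals$nHeads,
                                    vals$attentionDropout, inputSize)
  vals
}

#' Composite search fitness
#'
#' `alpha * (1 - valAccuracy) + beta * valLoss + gamma * flops / flopsMax`;
#' lower is better. A candidate exceeding the FLOPs normalizer is allowed
#' (ratio > 1) with a warning.
#'
#' @param valAccuracy validation accuracy in \[0,1\].
#' @param valLoss nonnegative validation cross-entropy.
#' @param flops candidate FLOPs.
#' @param weights a [FitnessWeights-class].
#' @return the scalar fitness.
#' @export
fitnessScore <- function(valAccuracy, valLoss, flops, weights) {
  stopifnot(is(weights, "FitnessWeights"))
  stopifnot(is.finite(valAccuracy), is.finite(valLoss), is.finite(flops),
            valAccuracy >= 0, valAccuracy <= 1, valLoss >= 0, flops >= 0)
  if (flops > weights@flopsMax)
    warning("candidate FLOPs exceed the flopsMax normalizer (ratio > 1)")
  weights@alpha * (1 - valAccuracy) + weights@beta * valLoss +
    weights@gamma * flops / weights@flopsMax
}

#' FLOPs of the largest configuration in the space
#'
#' Computed once, analytically, and used as the fitness normalizer.
#'
#' @param space a [SearchSpace-class] (the backbone menus are read from it).
#' @param inputSize input image side.
#' @param headCfg optional [CkanConfig-class] to include.
#' @return FLOPs of the maximal configuration.
#' @export
maxSpaceFlops <- function(space = hyperSearchSpace(), inputSize = 224,
                          headCfg = NULL) {
  pick <- function(nm) {
    j <- match(nm, space@dimNames)
    max(space@menus[[j]])
  }
  cfg <- backboneConfig(pick("widthMultiplier"), pick("depthwiseKernel"),
                        pick("embedDim"), pick("nHeads"), 0, inputSize)
  unname(countParamsFlops(cfg, headCfg)["flops"])
}

#' Evaluate one search candidate
#'
#' Decodes the position, builds the backbone (fixed-seed random weights)
#' and cKAN head, trains the head for `epochs` epochs on the training
#' split with the decoded learning rate / weight decay / batch size,
#' and scores validation accuracy, validation cross-entropy and analytic
#' FLOPs with [fitnessScore()]. Deterministic given `seed`; training
#' divergence (non-finite loss) yields +Inf fitness with a `diverged`
#' flag. The caller's RNG stream is left untouched.
#'
#' @param position search-space position.
#' @param data list(trainImages, trainLabels, valImages, valLabels);
#'   images as (B, H, W, 3) arrays in \[-1,1\].
#' @param space a [SearchSpace-class].
#' @param weights a [FitnessWeights-class].
#' @param headCfg a [CkanConfig-class].
#' @param epochs candidate training budget.
#' @param seed integer seed.
#' @return list(config, valAccuracy, valLoss, flops, fitness, diverged).
#' @export
evaluateCandidate <- function(position, data, space = hyperSearchSpace(),
                              weights = NULL, headCfg = NULL, epochs = 2,
                              seed = 1) {
  inputSize <- dim(data$trainImages)[2]
  dec <- decodePosition(position, space, inputSize)
  grid <- inputSize %/% 16
  if (is.null(headCfg)) headCfg <- ckanConfig()
  if (is.null(weights))
    weights <- fitnessWeights(flopsMax = maxSpaceFlops(space, inputSize, headCfg))
  flops <- unname(countParamsFlops(dec$backbone, headCfg)["flops"])
  res <- withSeed(seed, {
    bw <- initBackboneWeights(dec$backbone, seed = childSeed(seed, 11))
    ftr <- extractFeatures(data$trainImages, bw)
    fva <- extractFeatures(data$valImages, bw)
    if (epochs > 0) {
      tr <- trainHead(ftr, data$trainLabels, headCfg, epochs = epochs,
                      batchSize = dec$batchSize, lr = dec$learningRate,
                      weightDecay = dec$weightDecay, patience = epochs,
                      seed = childSeed(seed, 12))
      params <- tr$params
      diverged <- any(!is.finite(tr$history$trainLoss))
    } else {
      params <- ckanInit(headCfg, seed = childSeed(seed, 12))
      diverged <- FALSE
    }
    vp <- predictHead(fva, headCfg, params, "prob")
    vi <- cbind(seq_len(nrow(vp)), as.integer(data$valLabels) + 1L)
    valLoss <- -mean(log(pmax(vp[vi], 1e-12)))
    valAcc <- mean(max.col(vp, ties.method = "first") - 1L ==
                     as.integer(data$valLabels))
    list(valAcc = valAcc, valLoss = valLoss, diverged = diverged)
  })
  if (res$diverged || !is.finite(res$valLoss)) {
    fitness <- Inf
  } else {
    fitness <- fitnessScore(res$valAcc, res$valLoss, flops, weights)
  }
  list(config = dec, valAccuracy = res$valAcc, valLoss = res$valLoss,
       flops = flops, fitness = fitness, diverged = res$diverged)
}

#' Run the IWO hyperparameter search
#'
#' Minimizes the candidate fitness over the search space with
#' [iwoOptimize()]; emits the per-iteration best-fitness trace and the
#' decoded champion configuration. The trace is non-increasing (best-so-far
#' contract).
#'
#' @param data candidate-evaluation data, see [evaluateCandidate()].
#' @param space a [SearchSpace-class].
#' @param iwoCfg an [IWOConfig-class] (its seed drives the search).
#' @param weights a [FitnessWeights-class]; computed from the space when
#'   NULL.
#' @param headCfg a [CkanConfig-class].
#' @param epochs per-candidate training budget.
#' @param outDir optional directory for the trace CSV and champion YAML.
#' @return list(champion (decoded config), fitness, trace, result (raw
#'   optimizer output)).
#' @export
runSearch <- function(data, space = hyperSearchSpace(), iwoCfg = NULL,
                      weights = NULL, headCfg = ckanConfig(), epochs = 2,
                      outDir = NULL) {
  if (is.null(iwoCfg)) iwoCfg <- iwoConfig(populationSize = 6, tMax = 10)
  inputSize <- dim(data$trainImages)[2]
  if (is.null(weights))
    weights <- fitnessWeights(flopsMax = maxSpaceFlops(space, inputSize, headCfg))
  evalSeed <- childSeed(iwoCfg@seed, 101)
  objective <- function(position)
    evaluateCandidate(position, data, space, weights, headCfg, epochs,
                      seed = evalSeed)$fitness
  res <- iwoOptimize(objective, space, iwoCfg)
  champion <- decodePosition(res$bestPosition, space, inputSize)
  trace <- data.frame(iteration = seq_along(res$history) - 1L,
                      bestFitness = res$history)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    write.csv(trace, file.path(outDir, "search_trace.csv"), row.names = FALSE)
    champ <- champion[setdiff(names(champion), "backbone")]
    yaml::write_yaml(champ, file.path(outDir, "champion.yaml"))
  }
  list(champion = champion, fitness = res$bestFitness, trace = trace,
       result = res)
}
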
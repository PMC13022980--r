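## Central S4 classes. Validity methods enforce the domain invariants;
## user code should go through the constructor functions and accessors.

#' FundusImage: a square RGB fundus-style image with a severity grade
#'
#' Holds an H x W x 3 numeric pixel array together with its declared value
#' range (either \[0,1\] or \[-1,1\]), an integer diabetic-retinopathy
#' severity grade in 0..4 (0 = normal ... 4 = proliferative DR) and opaque
#' provenance metadata.
#'
#' @slot pixels numeric array, H x W x 3.
#' @slot valueRange numeric length-2, declared pixel interval.
#' @slot grade integer scalar in 0..4.
#' @slot id character identifier.
#' @slot meta list of provenance metadata (e.g. generator seed, lesion
#'   counts for synthetic images).
#' @export
setClass("FundusImage",
  representation(pixels = "array", valueRange = "numeric", grade = "integer",
                 id = "character", meta = "list"),
  prototype(valueRange = c(0, 1), grade = 0L, id = "", meta = list()))

setValidity("FundusImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3 || d[3] != 3) return("pixels must be an H x W x 3 array")
  if (d[1] != d[2]) return("image field must be square (H == W)")
  if (d[1] < 64) return("image side must be at least 64 pixels")
  if (length(object@valueRange) != 2 || diff(object@valueRange) <= 0)
    return("valueRange must be an ordered length-2 interval")
  rng <- range(object@pixels)
  eps <- 1e-9
  if (rng[1] < object@valueRange[1] - eps || rng[2] > object@valueRange[2] + eps)
    return(sprintf("pixel values [%g, %g] outside declared range [%g, %g]",
                   rng[1], rng[2], object@valueRange[1], object@valueRange[2]))
  if (!(object@grade %in% 0:4)) return("grade must be one of 0,1,2,3,4")
  TRUE
})

#' Construct a FundusImage
#'
#' @param pixels H x W x 3 numeric array.
#' @param grade integer severity grade in 0..4.
#' @param id identifier string.
#' @param valueRange declared pixel interval, default c(0, 1).
#' @param meta optional metadata list.
#' @return a [FundusImage-class] object.
#' @export
fundusImage <- function(pixels, grade, id = "img", valueRange = c(0, 1),
                        meta = list()) {
  new("FundusImage", pixels = pixels, valueRange = as.numeric(valueRange),
      grade = as.integer(grade), id = as.character(id), meta = meta)
}

#' @describeIn fundusImage pixel array accessor
#' @param object,x a FundusImage.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @export
setMethod("pixels", "FundusImage", function(object) object@pixels)

#' @export
setGeneric("grade", function(object) standardGeneric("grade"))
#' @describeIn fundusImage severity grade accessor
#' @export
setMethod("grade", "FundusImage", function(object) object@grade)

#' @export
setGeneric("valueRange", function(object) standardGeneric("valueRange"))
#' @describeIn fundusImage declared value range accessor
#' @export
setMethod("valueRange", "FundusImage", function(object) object@valueRange)

#' @export
setGeneric("imageId", function(object) standardGeneric("imageId"))
#' @describeIn fundusImage identifier accessor
#' @export
setMethod("imageId", "FundusImage", function(object) object@id)

setMethod("show", "FundusImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FundusImage '%s': %dx%dx3, grade %d, range [%g, %g]\n",
              object@id, d[1], d[2], object@grade,
              object@valueRange[1], object@valueRange[2]))
})

#' AugmentationParams: label-preserving augmentation settings
#'
#' Geometric (rotation within +/- maxRotation degrees, horizontal/vertical
#' flips, isotropic scaling, translation) and photometric (brightness,
#' contrast, saturation jitter) transform parameters. Each transform can be
#' toggled via the named logical vector `enabled`.
#'
#' @slot maxRotation nonnegative rotation tolerance in degrees (default 15).
#' @slot flipHorizontal,flipVertical flip probabilities in \[0,1\].
#' @slot scaleRange,translateRange,brightnessJitter,contrastJitter,saturationJitter
#'   ordered fraction intervals.
#' @slot enabled named logical vector over the seven transforms.
#' @export
setClass("AugmentationParams",
  representation(maxRotation = "numeric", flipHorizontal = "numeric",
                 flipVertical = "numeric", scaleRange = "numeric",
                 translateRange = "numeric", brightnessJitter = "numeric",
                 contrastJitter = "numeric", saturationJitter = "numeric",
                 enabled = "logical"))

.augNames <- c("rotation", "flipH", "flipV", "scale", "translate",
               "brightness", "contrast", "saturation")

setValidity("AugmentationParams", function(object) {
  if (object@maxRotation < 0) return("maxRotation must be >= 0")
  for (p in c(object@flipHorizontal, object@flipVertical))
    if (p < 0 || p > 1) return("flip probabilities must lie in [0,1]")
  ivs <- list(scaleRange = object@scaleRange, translateRange = object@translateRange,
              brightnessJitter = object@brightnessJitter,
              contrastJitter = object@contrastJitter,
              saturationJitter = object@saturationJitter)
  for (nm in names(ivs)) {
    iv <- ivs[[nm]]
    if (length(iv) != 2 || iv[1] > iv[2])
      return(sprintf("%s must be an ordered length-2 interval", nm))
  }
  if (!identical(sort(names(object@enabled)), sort(.augNames)))
    return("enabled must be a named logical over all transforms")
  TRUE
})

#' Construct augmentation parameters
#'
#' Defaults mirror the training-time augmentation protocol: rotations within
#' +/- 15 degrees, horizontal and vertical flips, mild scaling and
#' translation, and brightness/contrast/saturation jitter.
#'
#' @param maxRotation rotation tolerance in degrees.
#' @param flipHorizontal,flipVertical flip probabilities.
#' @param scaleRange isotropic scale factor interval.
#' @param translateRange translation interval as a fraction of image size.
#' @param brightnessJitter additive brightness interval (fraction of range).
#' @param contrastJitter,saturationJitter multiplicative jitter intervals.
#' @param enabled named logical vector; transforms absent from the names
#'   keep their default (TRUE).
#' @return an [AugmentationParams-class] object.
#' @export
augmentationParams <- function(maxRotation = 15, flipHorizontal = 0.5,
                               flipVertical = 0.5, scaleRange = c(0.9, 1.1),
                               translateRange = c(-0.05, 0.05),
                               brightnessJitter = c(-0.1, 0.1),
                               contrastJitter = c(0.9, 1.1),
                               saturationJitter = c(0.8, 1.2),
                               enabled = NULL) {
  en <- stats::setNames(rep(TRUE, length(.augNames)), .augNames)
  if (!is.null(enabled)) en[names(enabled)] <- enabled
  new("AugmentationParams", maxRotation = maxRotation,
      flipHorizontal = flipHorizontal, flipVertical = flipVertical,
      scaleRange = scaleRange, translateRange = translateRange,
      brightnessJitter = brightnessJitter, contrastJitter = contrastJitter,
      saturationJitter = saturationJitter, enabled = en)
}

#' LesionModel: grade-dependent lesion statistics for synthetic images
#'
#' Expected per-image lesion counts as a function of grade (Poisson means),
#' pixel-radius ranges and RGB color statistics for the three lesion classes
#' the severity scale is built on: microaneurysms (small round red dots),
#' hemorrhages (larger red bleeding spots) and exudates (yellow-white lipid
#' deposits). Rates are non-decreasing in grade and exactly zero at grade 0.
#'
#' @slot maRate,hemRate,exRate numeric length-5 Poisson means per grade 0..4.
#' @slot tuftRate numeric length-5 neovascular tuft means (grade 4 only by
#'   default).
#' @slot maRadius,hemRadius,exRadius pixel radius ranges.
#' @slot maColor,hemColor,exColor RGB means.
#' @slot colorSd scalar color standard deviation.
#' @export
setClass("LesionModel",
  representation(maRate = "numeric", hemRate = "numeric", exRate = "numeric",
                 tuftRate = "numeric", maRadius = "numeric",
                 hemRadius = "numeric", exRadius = "numeric",
                 maColor = "numeric", hemColor = "numeric", exColor = "numeric",
                 colorSd = "numeric"))

setValidity("LesionModel", function(object) {
  for (nm in c("maRate", "hemRate", "exRate", "tuftRate")) {
    r <- slot(object, nm)
    if (length(r) != 5) return(sprintf("%s must have one rate per grade", nm))
    if (any(r < 0)) return(sprintf("%s rates must be nonnegative", nm))
    if (any(diff(r) < 0)) return(sprintf("%s rates must be non-decreasing in grade", nm))
    if (r[1] != 0) return(sprintf("%s rate at grade 0 must be exactly 0", nm))
  }
  TRUE
})

#' Default lesion model
#'
#' Microaneurysm counts grow as 3 x grade, hemorrhages and exudates as
#' 2 x max(0, grade - 1), and neovascular tufts appear only at grade 4,
#' giving a monotone severity signal.
#'
#' @param maRate,hemRate,exRate,tuftRate optional length-5 Poisson means.
#' @return a [LesionModel-class] object.
#' @export
lesionModel <- function(maRate = 3 * (0:4),
                        hemRate = 2 * pmax(0, (0:4) - 1),
                        exRate = 2 * pmax(0, (0:4) - 1),
                        tuftRate = c(0, 0, 0, 0, 3)) {
  new("LesionModel", maRate = maRate, hemRate = hemRate, exRate = exRate,
      tuftRate = tuftRate, maRadius = c(1, 2), hemRadius = c(2, 5),
      exRadius = c(2, 4), maColor = c(0.45, 0.05, 0.05),
      hemColor = c(0.35, 0.04, 0.04), exColor = c(0.95, 0.93, 0.55),
      colorSd = 0.02)
}

#' DatasetSpec: composition of a synthetic dataset
#'
#' Either exact per-class counts or class probabilities (multinomial
#' sampling) for the five severity grades.
#'
#' @slot nImages total image count.
#' @slot classCounts integer length-5 counts, or NA to use probabilities.
#' @slot classProbs numeric length-5 probabilities summing to 1.
#' @slot imageSize image side in pixels.
#' @slot seed integer generator seed.
#' @export
setClass("DatasetSpec",
  representation(nImages = "integer", classCounts = "integer",
                 classProbs = "numeric", imageSize = "integer",
                 seed = "integer"))

setValidity("DatasetSpec", function(object) {
  if (object@nImages < 0) return("nImages must be nonnegative")
  if (!all(is.na(object@classCounts))) {
    if (length(object@classCounts) != 5 || any(object@classCounts < 0))
      return("classCounts must be 5 nonnegative integers")
    if (sum(object@classCounts) != object@nImages)
      return("classCounts must sum to nImages")
  } else {
    if (length(object@classProbs) != 5 || any(object@classProbs < 0))
      return("classProbs must be 5 nonnegative values")
    if (abs(sum(object@classProbs) - 1) > 1e-9)
      return("classProbs must sum to 1 (tolerance 1e-9)")
  }
  if (object@imageSize < 64) return("imageSize must be >= 64")
  TRUE
})

#' Construct a dataset specification
#'
#' @param nImages total number of images; inferred from `classCounts` when
#'   those are given.
#' @param classCounts optional exact per-class counts (length 5).
#' @param classProbs optional class probabilities (length 5, sum 1).
#' @param imageSize image side in pixels (default 224, the backbone input).
#' @param seed integer seed.
#' @return a [DatasetSpec-class] object.
#' @export
datasetSpec <- function(nImages = NULL, classCounts = NULL, classProbs = NULL,
                        imageSize = 224, seed = 1) {
  if (!is.null(classCounts)) {
    classCounts <- as.integer(classCounts)
    if (is.null(nImages)) nImages <- sum(classCounts)
    classProbs <- as.numeric(classCounts) / max(1, sum(classCounts))
  } else {
    if (is.null(classProbs))
      classProbs <- eyepacsClassProbs()
    classProbs <- classProbs / sum(classProbs)
    classCounts <- rep(NA_integer_, 5)
    if (is.null(nImages)) stop("nImages required when classCounts absent")
  }
  new("DatasetSpec", nImages = as.integer(nImages), classCounts = classCounts,
      classProbs = classProbs, imageSize = as.integer(imageSize),
      seed = as.integer(seed))
}

#' EyePACS-style class composition
#'
#' The five-grade class frequencies of the EyePACS screening collection
#' (normal 25783, mild 2459, moderate 5304, severe 878, proliferative 703),
#' as probabilities or scaled counts. These drive the default imbalance of
#' the synthetic datasets.
#'
#' @return numeric length-5 probability vector.
#' @export
eyepacsClassProbs <- function() {
  n <- eyepacsClassCounts()
  n / sum(n)
}

#' @describeIn eyepacsClassProbs raw per-grade counts.
#' @export
eyepacsClassCounts <- function() c(25783, 2459, 5304, 878, 703)

#' BackboneConfig: searchable feature-extractor hyperparameters
#'
#' The categorical/continuous hyperparameters of the hybrid backbone that
#' the IWO search tunes: ShuffleNet-V2 channel width multiplier, depthwise
#' kernel size, attention embedding dimension, number of attention heads and
#' attention dropout, plus the (fixed) input size.
#'
#' @slot widthMultiplier one of 0.5, 0.75, 1.0.
#' @slot depthwiseKernel one of 3, 5.
#' @slot embedDim one of 128, 256, 384.
#' @slot nHeads one of 4, 8.
#' @slot attentionDropout fraction in \[0, 0.3\].
#' @slot inputSize input image side in pixels (default 224).
#' @export
setClass("BackboneConfig",
  representation(widthMultiplier = "numeric", depthwiseKernel = "integer",
                 embedDim = "integer", nHeads = "integer",
                 attentionDropout = "numeric", inputSize = "integer"))

setValidity("BackboneConfig", function(object) {
  if (!(object@widthMultiplier %in% c(0.5, 0.75, 1.0)))
    return("widthMultiplier must be one of 0.5, 0.75, 1.0")
  if (!(object@depthwiseKernel %in% c(3L, 5L)))
    return("depthwiseKernel must be 3 or 5")
  if (!(object@embedDim %in% c(128L, 256L, 384L)))
    return("embedDim must be one of 128, 256, 384")
  if (!(object@nHeads %in% c(4L, 8L))) return("nHeads must be 4 or 8")
  if (object@embedDim %% object@nHeads != 0)
    return("embedDim must be divisible by nHeads")
  if (object@attentionDropout < 0 || object@attentionDropout > 0.3)
    return("attentionDropout must lie in [0, 0.3]")
  if (object@inputSize < 32 || object@inputSize %% 16 != 0)
    return("inputSize must be a multiple of 16 and >= 32")
  TRUE
})

#' Construct a backbone configuration
#'
#' @param widthMultiplier,depthwiseKernel,embedDim,nHeads,attentionDropout,inputSize
#'   see [BackboneConfig-class].
#' @return a [BackboneConfig-class] object.
#' @export
backboneConfig <- function(widthMultiplier = 0.5, depthwiseKernel = 3,
                           embedDim = 128, nHeads = 4, attentionDropout = 0,
                           inputSize = 224) {
  new("BackboneConfig", widthMultiplier = widthMultiplier,
      depthwiseKernel = as.integer(depthwiseKernel),
      embedDim = as.integer(embedDim), nHeads = as.integer(nHeads),
      attentionDropout = attentionDropout, inputSize = as.integer(inputSize))
}

#' FeatureMap: a rank-4 feature tensor
#'
#' Batch x height x width x channels numeric array flowing between the
#' backbone and the cKAN head.
#'
#' @slot data 4-dimensional numeric array.
#' @export
setClass("FeatureMap", representation(data = "array"))

setValidity("FeatureMap", function(object) {
  d <- dim(object@data)
  if (length(d) != 4) return("data must be a rank-4 array (B, H, W, C)")
  if (d[4] <= 0) return("channels must be positive")
  if (!all(is.finite(object@data))) return("feature values must be finite")
  TRUE
})

#' @export
featureMap <- function(data) new("FeatureMap", data = data)

#' @export
setGeneric("featureData", function(object) standardGeneric("featureData"))
#' @describeIn featureMap underlying array accessor
#' @param object a FeatureMap.
#' @export
setMethod("featureData", "FeatureMap", function(object) object@data)

setMethod("show", "FeatureMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("FeatureMap: %d x %d x %d x %d (batch, h, w, channels)\n",
              d[1], d[2], d[3], d[4]))
})

#' SplineBank: per-channel clamped cubic B-spline parameterization
#'
#' Each channel owns one univariate function represented in a clamped cubic
#' B-spline basis on a shared knot grid spanning a declared input interval.
#' With `nKnots` breakpoints and order 3 (degree 3, B-spline order 4 in the
#' de Boor counting) there are `nKnots + 2` basis functions per channel.
#' Inputs outside the interval are clamped to the boundary, so the functions
#' extrapolate by their boundary value.
#'
#' @slot knots strictly increasing breakpoints spanning `interval`.
#' @slot order spline polynomial degree, fixed at 3 (cubic).
#' @slot coefficients channels x nBasis coefficient matrix.
#' @slot interval declared input interval (default \[-2, 2\]).
#' @export
setClass("SplineBank",
  representation(knots = "numeric", order = "integer",
                 coefficients = "matrix", interval = "numeric"))

setValidity("SplineBank", function(object) {
  if (any(diff(object@knots) <= 0)) return("knots must be strictly increasing")
  if (object@order != 3L) return("order must be 3 (cubic)")
  nb <- length(object@knots) + object@order - 1
  if (ncol(object@coefficients) != nb)
    return(sprintf("coefficients must have %d columns (got %d)",
                   nb, ncol(object@coefficients)))
  if (length(object@interval) != 2 || diff(object@interval) <= 0)
    return("interval must be an ordered length-2 interval")
  TRUE
})

setMethod("show", "SplineBank", function(object) {
  cat(sprintf(
    "SplineBank: %d channels, cubic, %d knots on [%g, %g], %d basis functions\n",
    nrow(object@coefficients), length(object@knots),
    object@interval[1], object@interval[2], ncol(object@coefficients)))
})

#' CkanConfig: convolutional Kolmogorov-Arnold head configuration
#'
#' Channel layout of the five-stage cKAN head (condenser 1x1 conv,
#' depthwise + spline function bank, superposition mixer 1x1 conv, global
#' average pooling, hidden linear projection + softmax) together with the
#' regularization weights of the training objective
#' `O_total = O_pred + lambda * (mu1 * L1(phi) + mu2 * S(phi))`.
#'
#' @slot inChannels input channels (256 from the backbone).
#' @slot condensedChannels channels after the condenser (128).
#' @slot outChannels channels after the superposition mixer (256).
#' @slot nClasses number of severity grades (5).
#' @slot hiddenUnits hidden width of the projection head (128).
#' @slot lambda,mu1,mu2 nonnegative regularization weights.
#' @slot dropout dropout fraction on the hidden layer (default 0.3).
#' @slot nKnots spline breakpoints per channel (8).
#' @slot splineInterval spline input interval (default \[-2, 2\]).
#' @export
setClass("CkanConfig",
  representation(inChannels = "integer", condensedChannels = "integer",
                 outChannels = "integer", nClasses = "integer",
                 hiddenUnits = "integer", lambda = "numeric", mu1 = "numeric",
                 mu2 = "numeric", dropout = "numeric", nKnots = "integer",
                 splineInterval = "numeric"))

setValidity("CkanConfig", function(object) {
  for (nm in c("inChannels", "condensedChannels", "outChannels", "nClasses",
               "hiddenUnits"))
    if (slot(object, nm) <= 0) return(sprintf("%s must be positive", nm))
  for (nm in c("lambda", "mu1", "mu2"))
    if (slot(object, nm) < 0) return(sprintf("%s must be nonnegative", nm))
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must lie in [0, 1)")
  if (object@nKnots < 4) return("need at least 4 knots for a cubic spline")
  TRUE
})

#' Construct a cKAN head configuration
#'
#' @param inChannels,condensedChannels,outChannels,nClasses,hiddenUnits
#'   channel layout (defaults follow the published tensor flow:
#'   256 -> 128 -> 256 -> 5).
#' @param lambda,mu1,mu2 regularization weights (defaults 1e-4, 1, 1).
#' @param dropout hidden-layer dropout fraction.
#' @param nKnots spline breakpoints (default 8).
#' @param splineInterval spline input interval.
#' @return a [CkanConfig-class] object.
#' @export
ckanConfig <- function(inChannels = 256, condensedChannels = 128,
                       outChannels = 256, nClasses = 5, hiddenUnits = 128,
                       lambda = 1e-4, mu1 = 1, mu2 = 1, dropout = 0.3,
                       nKnots = 8, splineInterval = c(-2, 2)) {
  new("CkanConfig", inChannels = as.integer(inChannels),
      condensedChannels = as.integer(condensedChannels),
      outChannels = as.integer(outChannels), nClasses = as.integer(nClasses),
      hiddenUnits = as.integer(hiddenUnits), lambda = lambda, mu1 = mu1,
      mu2 = mu2, dropout = dropout, nKnots = as.integer(nKnots),
      splineInterval = as.numeric(splineInterval))
}

#' SearchSpace: a bounded box with per-dimension kinds
#'
#' Each dimension is continuous, log-continuous (bounds and positions live
#' on the log10 scale) or categorical (continuous relaxation on
#' \[0, menu size), decoded by floor).
#'
#' @slot lower,upper numeric bounds (lower < upper, except degenerate
#'   dimensions which are allowed with a warning at initialization).
#' @slot kind character: "continuous", "log" or "categorical".
#' @slot menus list of menus (non-empty for categorical dimensions).
#' @slot dimNames dimension names.
#' @export
setClass("SearchSpace",
  representation(lower = "numeric", upper = "numeric", kind = "character",
                 menus = "list", dimNames = "character"))

setValidity("SearchSpace", function(object) {
  d <- length(object@lower)
  if (length(object@upper) != d || length(object@kind) != d ||
      length(object@menus) != d || length(object@dimNames) != d)
    return("all per-dimension fields must have equal length")
  if (any(object@lower > object@upper)) return("need lower <= upper per dimension")
  if (!all(object@kind %in% c("continuous", "log", "categorical")))
    return("kind must be continuous, log or categorical")
  for (j in seq_len(d))
    if (object@kind[j] == "categorical" && length(object@menus[[j]]) == 0)
      return("categorical menus must be non-empty")
  TRUE
})

#' Construct a search space
#'
#' @param lower,upper numeric bounds per dimension. For categorical
#'   dimensions the bounds are derived from the menu.
#' @param kind per-dimension kind.
#' @param menus list of menus (NULL entries for non-categorical dims).
#' @param dimNames optional names.
#' @return a [SearchSpace-class] object.
#' @export
searchSpace <- function(lower, upper, kind = NULL, menus = NULL,
                        dimNames = NULL) {
  d <- length(lower)
  if (is.null(kind)) kind <- rep("continuous", d)
  if (is.null(menus)) menus <- rep(list(NULL), d)
  for (j in seq_len(d)) {
    if (kind[j] == "categorical") {
      lower[j] <- 0
      upper[j] <- length(menus[[j]])
    }
  }
  if (is.null(dimNames)) dimNames <- paste0("x", seq_len(d))
  new("SearchSpace", lower = as.numeric(lower), upper = as.numeric(upper),
      kind = kind, menus = menus, dimNames = dimNames)
}

#' @export
setGeneric("spaceDim", function(object) standardGeneric("spaceDim"))
#' @describeIn searchSpace number of dimensions
#' @param object a SearchSpace.
#' @export
setMethod("spaceDim", "SearchSpace", function(object) length(object@lower))

setMethod("show", "SearchSpace", function(object) {
  cat(sprintf("SearchSpace: %d dimensions\n", spaceDim(object)))
  for (j in seq_len(spaceDim(object)))
    cat(sprintf("  %-18s %-11s [%g, %g]\n", object@dimNames[j], object@kind[j],
                object@lower[j], object@upper[j]))
})

#' IWOConfig: Improved Whale Optimization settings
#'
#' Population metaheuristic settings: population size and iteration budget,
#' the nonlinear convergence-factor smoothness `m`, the cosine inertia
#' cycle size `lCycle`, the logarithmic-spiral constant `b`, the Cauchy
#' mutation scale and crossover rate, and the optimal-based feedback
#' threshold and population fraction it applies to.
#'
#' @slot populationSize whales (menu 20/30/40 in the published settings).
#' @slot tMax iterations (menu 30/50/70).
#' @slot m convergence-curve smoothness (> 0).
#' @slot lCycle inertia-weight cycle size.
#' @slot b spiral constant.
#' @slot cauchyScale Cauchy mutation scale in \[0.1, 1.0\].
#' @slot crossoverRate per-dimension mutation probability.
#' @slot feedbackThreshold feedback trigger threshold in \[0,1\].
#' @slot feedbackFraction fraction of the (worst) population feedback
#'   applies to.
#' @slot convergence "nonlinear" (exponential schedule) or "linear".
#' @slot inertia "cosine", "constant" or "lineardecay" (0.9 -> 0.4).
#' @slot mutation logical; disable to reduce to the vanilla algorithm.
#' @slot seed integer seed.
#' @export
setClass("IWOConfig",
  representation(populationSize = "integer", tMax = "integer", m = "numeric",
                 lCycle = "numeric", b = "numeric", cauchyScale = "numeric",
                 crossoverRate = "numeric", feedbackThreshold = "numeric",
                 feedbackFraction = "numeric", convergence = "character",
                 inertia = "character", mutation = "logical", seed = "integer"))

setValidity("IWOConfig", function(object) {
  if (object@populationSize < 2) return("populationSize must be >= 2")
  if (object@tMax < 1) return("tMax must be >= 1")
  if (object@m <= 0) return("m must be > 0")
  if (object@cauchyScale < 0.1 || object@cauchyScale > 1.0)
    return("cauchyScale must lie in [0.1, 1.0]")
  if (object@crossoverRate < 0 || object@crossoverRate > 1)
    return("crossoverRate must lie in [0,1]")
  if (object@feedbackFraction < 0 || object@feedbackFraction > 1)
    return("feedbackFraction must lie in [0,1]")
  if (!(object@convergence %in% c("nonlinear", "linear")))
    return("convergence must be 'nonlinear' or 'linear'")
  if (!(object@inertia %in% c("cosine", "constant", "lineardecay")))
    return("inertia must be 'cosine', 'constant' or 'lineardecay'")
  TRUE
})

#' Construct an IWO configuration
#'
#' @param populationSize,tMax,m,lCycle,b,cauchyScale,crossoverRate,feedbackThreshold,feedbackFraction,convergence,inertia,mutation,seed
#'   see [IWOConfig-class].
#' @return an [IWOConfig-class] object.
#' @export
iwoConfig <- function(populationSize = 20, tMax = 50, m = 0.5, lCycle = 1,
                      b = 1, cauchyScale = 0.1, crossoverRate = 0.1,
                      feedbackThreshold = 0.5, feedbackFraction = 0.2,
                      convergence = "nonlinear", inertia = "cosine",
                      mutation = TRUE, seed = 1) {
  new("IWOConfig", populationSize = as.integer(populationSize),
      tMax = as.integer(tMax), m = m, lCycle = lCycle, b = b,
      cauchyScale = cauchyScale, crossoverRate = crossoverRate,
      feedbackThreshold = feedbackThreshold,
      feedbackFraction = feedbackFraction, convergence = convergence,
      inertia = inertia, mutation = mutation, seed = as.integer(seed))
}

#' FitnessWeights: composite search-fitness trade-off weights
#'
#' The candidate fitness is
#' `alpha * (1 - ValAccuracy) + beta * ValLoss + gamma * FLOPs / FLOPsMax`
#' (lower is better), trading classification quality against the
#' computational complexity of the candidate feature extractor.
#'
#' @slot alpha,beta,gamma nonnegative trade-off weights (alpha+beta+gamma > 0).
#' @slot flopsMax positive FLOPs normalizer (largest config in the space).
#' @export
setClass("FitnessWeights",
  representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
                 flopsMax = "numeric"))

setValidity("FitnessWeights", function(object) {
  if (any(c(object@alpha, object@beta, object@gamma) < 0))
    return("weights must be nonnegative")
  if (object@alpha + object@beta + object@gamma <= 0)
    return("alpha + beta + gamma must be > 0")
  if (object@flopsMax <= 0) return("flopsMax must be positive")
  TRUE
})

#' Construct fitness weights
#'
#' @param alpha,beta,gamma trade-off weights (defaults 0.6/0.3/0.1,
#'   accuracy-dominant).
#' @param flopsMax FLOPs normalizer.
#' @return a [FitnessWeights-class] object.
#' @export
fitnessWeights <- function(alpha = 0.6, beta = 0.3, gamma = 0.1,
                           flopsMax = 1) {
  new("FitnessWeights", alpha = alpha, beta = beta, gamma = gamma,
      flopsMax = flopsMax)
}

#' FoldAssignment: stratified cross-validation fold structure
#'
#' Every sample is a test sample in exactly one fold; within each fold the
#' remaining samples are split 90/10 into train/validation, stratified by
#' class.
#'
#' @slot testFold integer fold index (1..k) per sample.
#' @slot folds list of k lists with integer `train`, `val`, `test` indices.
#' @slot k number of folds.
#' @export
setClass("FoldAssignment",
  representation(testFold = "integer", folds = "list", k = "integer"))

setValidity("FoldAssignment", function(object) {
  k <- object@k
  if (length(object@folds) != k) return("folds list must have k entries")
  n <- length(object@testFold)
  seen <- integer(n)
  for (f in seq_len(k)) {
    fd <- object@folds[[f]]
    if (!all(c("train", "val", "test") %in% names(fd)))
      return("each fold needs train/val/test indices")
    if (length(intersect(fd$train, fd$test)) || length(intersect(fd$val, fd$test)) ||
        length(intersect(fd$train, fd$val)))
      return("train/val/test must be disjoint within a fold")
    seen[fd$test] <- seen[fd$test] + 1L
  }
  if (!all(seen == 1L)) return("every sample must be a test sample exactly once")
  TRUE
})

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d samples, %d folds\n",
              length(object@testFold), object@k))
})
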
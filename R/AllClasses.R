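#' @import methods
NULL

#' Preprocessing configuration
#'
#' Parameters for colour-to-grayscale conversion and contrast enhancement.
#' Grayscale uses a weighted sum of the red, green and blue channels; the
#' default weights are the NTSC luminance coefficients (0.299, 0.587, 0.114),
#' which approximate perceived brightness. Contrast enhancement is a linear
#' percentile stretch: the \code{lowerPercentile} intensity maps to 0 and the
#' \code{upperPercentile} intensity to 255, with clipping.
#'
#' @slot grayCoefficients numeric(3), non-negative channel weights
#'   (red, green, blue).
#' @slot roundingMode currently only \code{"nearest"} (half away from zero).
#' @slot contrastMethod currently only \code{"percentile_stretch"}.
#' @slot lowerPercentile,upperPercentile stretch anchor percentiles in
#'   [0, 100] with lower < upper.
#' @export
setClass("PreprocessConfig",
  representation(grayCoefficients = "numeric", roundingMode = "character",
                 contrastMethod = "character", lowerPercentile = "numeric",
                 upperPercentile = "numeric"))

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (length(object@grayCoefficients) != 3L || any(!is.finite(object@grayCoefficients)))
    msg <- c(msg, "grayCoefficients must be 3 finite numbers")
  else if (any(object@grayCoefficients < 0))
    msg <- c(msg, "grayCoefficients must be non-negative")
  if (!identical(object@roundingMode, "nearest"))
    msg <- c(msg, "roundingMode must be 'nearest'")
  if (!identical(object@contrastMethod, "percentile_stretch"))
    msg <- c(msg, "contrastMethod must be 'percentile_stretch'")
  lp <- object@lowerPercentile; up <- object@upperPercentile
  if (length(lp) != 1L || length(up) != 1L || lp < 0 || up > 100 || lp >= up)
    msg <- c(msg, "percentiles must satisfy 0 <= lower < upper <= 100")
  if (length(msg)) msg else TRUE
})

#' @param grayCoefficients,roundingMode,contrastMethod,lowerPercentile,upperPercentile
#'   see slot documentation.
#' @return A \code{PreprocessConfig} object.
#' @examples
#' cfg <- PreprocessConfig()
#' grayCoefficients(cfg)
#' @rdname PreprocessConfig-class
#' @export
PreprocessConfig <- function(grayCoefficients = c(0.299, 0.587, 0.114),
                             roundingMode = "nearest",
                             contrastMethod = "percentile_stretch",
                             lowerPercentile = 1, upperPercentile = 99) {
  new("PreprocessConfig", grayCoefficients = as.numeric(grayCoefficients),
      roundingMode = roundingMode, contrastMethod = contrastMethod,
      lowerPercentile = as.numeric(lowerPercentile),
      upperPercentile = as.numeric(upperPercentile))
}

#' Labeled single-cell image datastore
#'
#' The unit of data exchanged between all pipeline stages: a list of per-cell
#' images (grayscale matrices or H x W x 3 colour arrays, intensities in
#' [0, 255]) with class labels and provenance paths.
#'
#' @slot images list of numeric matrices (grayscale) or 3-d arrays (colour).
#' @slot labels character vector of class labels, one per image.
#' @slot sourcePaths character vector of unique provenance strings.
#' @slot classNames ordered unique label universe (may include classes not
#'   present in this subset, e.g. in an empty validation fold).
#' @export
setClass("CellImageSet",
  representation(images = "list", labels = "character",
                 sourcePaths = "character", classNames = "character"))

setValidity("CellImageSet", function(object) {
  msg <- character()
  n <- length(object@images)
  if (length(object@labels) != n || length(object@sourcePaths) != n)
    msg <- c(msg, "images, labels and sourcePaths must have equal length")
  if (length(object@classNames) == 0L)
    msg <- c(msg, "classNames must be non-empty")
  if (anyDuplicated(object@classNames))
    msg <- c(msg, "classNames must be unique")
  if (n > 0 && !all(object@labels %in% object@classNames))
    msg <- c(msg, "every label must appear in classNames")
  if (anyDuplicated(object@sourcePaths))
    msg <- c(msg, "sourcePaths must be unique")
  if (length(msg)) msg else TRUE
})

#' @param images,labels,sourcePaths,classNames see slot documentation;
#'   \code{classNames} defaults to the sorted unique labels.
#' @return A \code{CellImageSet}.
#' @rdname CellImageSet-class
#' @export
CellImageSet <- function(images, labels, sourcePaths = NULL, classNames = NULL) {
  if (is.null(sourcePaths))
    sourcePaths <- sprintf("record_%05d", seq_along(images))
  if (is.null(classNames)) classNames <- sort(unique(labels))
  new("CellImageSet", images = images, labels = as.character(labels),
      sourcePaths = as.character(sourcePaths),
      classNames = as.character(classNames))
}

#' Train/validation/test split specification
#'
#' Fractions default to 0.6:0.2:0.2 with per-class stratification.
#' Within each class the validation and test folds receive
#' \code{floor(fraction * n)} images and the remainder goes to training.
#'
#' @slot trainFraction,validateFraction,testFraction fractions in [0, 1]
#'   summing to 1.
#' @slot stratified logical; split within each class.
#' @slot seed integer RNG seed for the shuffle.
#' @export
setClass("SplitSpec",
  representation(trainFraction = "numeric", validateFraction = "numeric",
                 testFraction = "numeric", stratified = "logical",
                 seed = "integer"))

setValidity("SplitSpec", function(object) {
  f <- c(object@trainFraction, object@validateFraction, object@testFraction)
  msg <- character()
  if (any(f < 0) || any(f > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9) msg <- c(msg, "fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' @param trainFraction,validateFraction,testFraction,stratified,seed see
#'   slot documentation.
#' @return A \code{SplitSpec}.
#' @rdname SplitSpec-class
#' @export
SplitSpec <- function(trainFraction = 0.6, validateFraction = 0.2,
                      testFraction = 0.2, stratified = TRUE, seed = 1L) {
  new("SplitSpec", trainFraction = trainFraction,
      validateFraction = validateFraction, testFraction = testFraction,
      stratified = isTRUE(stratified), seed = as.integer(seed))
}

#' Fine-tuning configuration
#'
#' Optimiser and schedule for fine-tuning a backbone's trainable layers.
#' The supported optimisers are stochastic gradient descent with momentum
#' (\code{"sgdm"}, momentum 0.9), \code{"adam"} and \code{"rmsprop"}.
#' Defaults sit inside the ranges customary for transfer learning on small
#' image sets: learning rate 1e-3, 30 epochs, mini-batches of 32.
#'
#' @slot optimizer one of \code{"sgdm"}, \code{"adam"}, \code{"rmsprop"}.
#' @slot learningRate positive step size (constant schedule).
#' @slot maxEpochs maximum training epochs.
#' @slot miniBatchSize observations per mini-batch.
#' @slot seed integer seed governing initialisation and batch order.
#' @slot earlyStoppingPatience epochs without validation-accuracy improvement
#'   before stopping.
#' @slot classWeighting logical; weight the loss by inverse class frequency
#'   (off by default).
#' @export
setClass("TrainConfig",
  representation(optimizer = "character", learningRate = "numeric",
                 maxEpochs = "integer", miniBatchSize = "integer",
                 seed = "integer", earlyStoppingPatience = "integer",
                 classWeighting = "logical"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (!object@optimizer %in% c("sgdm", "adam", "rmsprop"))
    msg <- c(msg, "optimizer must be one of sgdm, adam, rmsprop")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (object@miniBatchSize < 1L) msg <- c(msg, "miniBatchSize must be >= 1")
  if (object@earlyStoppingPatience < 1L)
    msg <- c(msg, "earlyStoppingPatience must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param optimizer,learningRate,maxEpochs,miniBatchSize,seed,earlyStoppingPatience,classWeighting
#'   see slot documentation.
#' @return A \code{TrainConfig}.
#' @rdname TrainConfig-class
#' @export
TrainConfig <- function(optimizer = "adam", learningRate = 1e-3,
                        maxEpochs = 30L, miniBatchSize = 32L, seed = 1L,
                        earlyStoppingPatience = 10L, classWeighting = FALSE) {
  new("TrainConfig", optimizer = optimizer, learningRate = learningRate,
      maxEpochs = as.integer(maxEpochs),
      miniBatchSize = as.integer(miniBatchSize), seed = as.integer(seed),
      earlyStoppingPatience = as.integer(earlyStoppingPatience),
      classWeighting = isTRUE(classWeighting))
}

#' Backbone specification
#'
#' One entry of the backbone registry: either a published ImageNet-scale
#' architecture (whose convolutional trunk must be supplied as a pretrained
#' weight artifact) or a desk-scale surrogate CNN whose trunk is materialised
#' deterministically from \code{weightSeed}. A trunk is a stack of
#' convolution (3x3, same padding) + ReLU + 2x2 mean-pool blocks; fine-tuning
#' updates the dense block and classification head appended on top while the
#' trunk stays frozen, the standard small-data transfer-learning regime.
#'
#' @slot name unique registry identifier.
#' @slot inputSize square input side in pixels (>= 32).
#' @slot pretrainedSource \code{"imagenet_weights"}, \code{"places365_weights"}
#'   or \code{"random_init"}.
#' @slot frozenDepth fraction of weighted layers (counted from the input)
#'   kept fixed during fine-tuning.
#' @slot convFilters integer vector of filters per trunk block
#'   (empty for artifact-backed architectures).
#' @slot hiddenUnits width of the trainable dense block.
#' @slot weightSeed seed materialising a random-init trunk.
#' @export
setClass("BackboneSpec",
  representation(name = "character", inputSize = "integer",
                 pretrainedSource = "character", frozenDepth = "numeric",
                 convFilters = "integer", hiddenUnits = "integer",
                 weightSeed = "integer"))

setValidity("BackboneSpec", function(object) {
  msg <- character()
  if (object@inputSize < 32L) msg <- c(msg, "inputSize must be >= 32")
  if (!object@pretrainedSource %in%
      c("imagenet_weights", "places365_weights", "random_init"))
    msg <- c(msg, "unknown pretrainedSource")
  if (object@frozenDepth < 0 || object@frozenDepth > 1)
    msg <- c(msg, "frozenDepth must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' A fine-tuned backbone
#'
#' One backbone after fine-tuning: predicts a class label and a normalised
#' per-class score vector for an image. Prediction is deterministic once
#' training completes.
#'
#' @slot backbone the \code{BackboneSpec} trained.
#' @slot classNames ordered label universe the model emits.
#' @slot trunk frozen convolutional weights (list of W/b per block).
#' @slot dense trainable parameters (dense block and softmax head).
#' @slot featNorm feature standardisation (mean/sd from the training fold).
#' @slot trainingLog per-epoch loss/accuracy on train and validation folds.
#' @slot trainConfig the \code{TrainConfig} used.
#' @slot bestEpoch epoch whose weights were retained (best validation
#'   accuracy).
#' @export
setClass("FineTunedModel",
  representation(backbone = "BackboneSpec", classNames = "character",
                 trunk = "list", dense = "list", featNorm = "list",
                 trainingLog = "data.frame", trainConfig = "TrainConfig",
                 bestEpoch = "integer"))

#' Per-model predictions
#'
#' Ordered predictions of one model over a datastore: predicted label and a
#' normalised score vector per record.
#'
#' @slot recordIds provenance identifiers, aligned with the input datastore.
#' @slot predictedLabels argmax labels.
#' @slot scores numeric matrix (records x classes), rows sum to 1.
#' @slot classNames score column universe.
#' @slot modelId identifier of the producing model.
#' @export
setClass("PredictionSet",
  representation(recordIds = "character", predictedLabels = "character",
                 scores = "matrix", classNames = "character",
                 modelId = "character"))

setValidity("PredictionSet", function(object) {
  msg <- character()
  n <- length(object@recordIds)
  if (length(object@predictedLabels) != n || nrow(object@scores) != n)
    msg <- c(msg, "recordIds, predictedLabels and scores must align")
  if (ncol(object@scores) != length(object@classNames))
    msg <- c(msg, "score columns must match classNames")
  if (n > 0) {
    if (any(object@scores < -1e-12))
      msg <- c(msg, "scores must be non-negative")
    if (any(abs(rowSums(object@scores) - 1) > 1e-6))
      msg <- c(msg, "score rows must sum to 1 (within 1e-6)")
    if (!all(object@predictedLabels %in% object@classNames))
      msg <- c(msg, "predicted labels must be in classNames")
  }
  if (length(msg)) msg else TRUE
})

#' Vote tally across models
#'
#' Per-record counts of predicted labels across an ensemble of models.
#'
#' @slot recordIds record identifiers (order preserved).
#' @slot counts integer matrix (records x classes); each row sums to
#'   \code{nModels}.
#' @slot classNames class universe.
#' @slot nModels number of voting models.
#' @export
setClass("VoteTally",
  representation(recordIds = "character", counts = "matrix",
                 classNames = "character", nModels = "integer"))

setValidity("VoteTally", function(object) {
  msg <- character()
  if (nrow(object@counts) != length(object@recordIds) ||
      ncol(object@counts) != length(object@classNames))
    msg <- c(msg, "counts must be records x classes")
  if (nrow(object@counts) > 0) {
    if (any(object@counts < 0) || any(object@counts != round(object@counts)))
      msg <- c(msg, "counts must be non-negative integers")
    if (any(rowSums(object@counts) != object@nModels))
      msg <- c(msg, "each row of counts must sum to nModels")
  }
  if (length(msg)) msg else TRUE
})

#' Ensemble (majority-vote) prediction
#'
#' Fused prediction per record: the plurality winner, its vote count, a flag
#' marking records whose winner required tie-breaking, and the mean score
#' vector across models.
#'
#' @slot recordIds record identifiers.
#' @slot predictedLabels winning labels.
#' @slot winningCounts votes received by each winner.
#' @slot tieBroken TRUE where two or more classes shared the maximum count.
#' @slot meanScores mean normalised score vectors across models.
#' @slot classNames class universe.
#' @slot nModels number of models fused.
#' @export
setClass("EnsemblePrediction",
  representation(recordIds = "character", predictedLabels = "character",
                 winningCounts = "integer", tieBroken = "logical",
                 meanScores = "matrix", classNames = "character",
                 nModels = "integer"))

#' Confusion chart
#'
#' Cross-tabulation of true versus predicted classes; rows are true classes,
#' columns predicted, the diagonal holds correct classifications.
#'
#' @slot classNames ordered labels for both axes.
#' @slot counts non-negative integer matrix, rows = truth.
#' @export
setClass("ConfusionChart",
  representation(classNames = "character", counts = "matrix"))

setValidity("ConfusionChart", function(object) {
  msg <- character()
  k <- length(object@classNames)
  if (nrow(object@counts) != k || ncol(object@counts) != k)
    msg <- c(msg, "counts must be a square classes x classes matrix")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' Experiment report
#'
#' Result bundle of one classification experiment: per-model and ensemble
#' test accuracies (percent), per-class accuracy, the ensemble confusion
#' chart, and a full configuration snapshot (with hash) for reproducibility.
#'
#' @slot name experiment label.
#' @slot modelAccuracies named numeric, overall test accuracy (%) per model.
#' @slot ensembleAccuracy ensemble overall test accuracy (%).
#' @slot perClassAccuracy named numeric, ensemble per-class accuracy (%).
#' @slot balancedAccuracy mean of per-class accuracies (%), informative under
#'   class imbalance where plain accuracy is optimistic.
#' @slot chart ensemble \code{ConfusionChart} on the test fold.
#' @slot config configuration snapshot (split, training, backbones, seeds,
#'   md5 hash).
#' @slot notes free-text annotations (e.g. one-vs-rest imbalance ratio).
#' @export
setClass("ExperimentReport",
  representation(name = "character", modelAccuracies = "numeric",
                 ensembleAccuracy = "numeric", perClassAccuracy = "numeric",
                 balancedAccuracy = "numeric", chart = "ConfusionChart",
                 config = "list", notes = "character"))

#' Synthetic cell phenotype parameters
#'
#' Distributional parameters of one synthetic class of Giemsa-Wright-style
#' mononuclear cells: roughly round cells on a pale background, with a
#' darker, textured nucleus. Instance values are drawn per image.
#'
#' @slot cellRadiusMean,cellRadiusSd cell radius (pixels).
#' @slot nucleusRatioMean,nucleusRatioSd nucleus-to-cell area ratio in (0, 1).
#' @slot eccentricityMean,eccentricitySd ellipse eccentricity in [0, 1).
#' @slot chromatinTextureScale correlation length (pixels) of intra-nuclear
#'   intensity noise; 0 disables texture.
#' @slot stainHueJitter sd of the per-image multiplicative hue perturbation.
#' @slot backgroundLevel background intensity in [0, 255].
#' @export
setClass("CellPhenotypeParams",
  representation(cellRadiusMean = "numeric", cellRadiusSd = "numeric",
                 nucleusRatioMean = "numeric", nucleusRatioSd = "numeric",
                 eccentricityMean = "numeric", eccentricitySd = "numeric",
                 chromatinTextureScale = "numeric", stainHueJitter = "numeric",
                 backgroundLevel = "numeric"))

setValidity("CellPhenotypeParams", function(object) {
  msg <- character()
  if (object@cellRadiusMean <= 0) msg <- c(msg, "cellRadiusMean must be > 0")
  if (object@cellRadiusSd < 0 || object@nucleusRatioSd < 0 ||
      object@eccentricitySd < 0)
    msg <- c(msg, "standard deviations must be >= 0")
  if (object@nucleusRatioMean <= 0 || object@nucleusRatioMean >= 1)
    msg <- c(msg, "nucleusRatioMean must lie in (0, 1)")
  if (object@eccentricityMean < 0 || object@eccentricityMean >= 1)
    msg <- c(msg, "eccentricityMean must lie in [0, 1)")
  if (object@chromatinTextureScale < 0)
    msg <- c(msg, "chromatinTextureScale must be >= 0")
  if (object@backgroundLevel < 0 || object@backgroundLevel > 255)
    msg <- c(msg, "backgroundLevel must lie in [0, 255]")
  if (length(msg)) msg else TRUE
})

#' @param cellRadiusMean,cellRadiusSd,nucleusRatioMean,nucleusRatioSd,eccentricityMean,eccentricitySd,chromatinTextureScale,stainHueJitter,backgroundLevel
#'   see slot documentation.
#' @return A \code{CellPhenotypeParams}.
#' @rdname CellPhenotypeParams-class
#' @export
CellPhenotypeParams <- function(cellRadiusMean = 17, cellRadiusSd = 1.8,
                                nucleusRatioMean = 0.55, nucleusRatioSd = 0.05,
                                eccentricityMean = 0.3, eccentricitySd = 0.1,
                                chromatinTextureScale = 2.5,
                                stainHueJitter = 0.05,
                                backgroundLevel = 235) {
  new("CellPhenotypeParams", cellRadiusMean = cellRadiusMean,
      cellRadiusSd = cellRadiusSd, nucleusRatioMean = nucleusRatioMean,
      nucleusRatioSd = nucleusRatioSd, eccentricityMean = eccentricityMean,
      eccentricitySd = eccentricitySd,
      chromatinTextureScale = chromatinTextureScale,
      stainHueJitter = stainHueJitter, backgroundLevel = backgroundLevel)
}

#' Synthetic dataset specification
#'
#' Defines a seeded synthetic dataset: per-class phenotype parameters, images
#' per class, canvas size and the master seed. Use \code{\link{syntheticSpec}}
#' to build one from a baseline phenotype and a class-separation parameter.
#'
#' @slot classParams named list of \code{CellPhenotypeParams}, one per class.
#' @slot nPerClass images per class.
#' @slot imageSize square canvas side in pixels.
#' @slot separationDelta the class-separation parameter the classParams were
#'   built with (0 means all classes share identical parameters).
#' @slot seed master seed; per-image seeds derive from it by a counter
#'   scheme, so datasets are reproducible element-wise.
#' @export
setClass("SyntheticDatasetSpec",
  representation(classParams = "list", nPerClass = "integer",
                 imageSize = "integer", separationDelta = "numeric",
                 seed = "integer"))

setValidity("SyntheticDatasetSpec", function(object) {
  msg <- character()
  if (length(object@classParams) < 2L)
    msg <- c(msg, "at least 2 classes are required")
  if (is.null(names(object@classParams)) ||
      anyDuplicated(names(object@classParams)))
    msg <- c(msg, "classParams must be uniquely named")
  if (!all(vapply(object@classParams, is, logical(1), "CellPhenotypeParams")))
    msg <- c(msg, "classParams must contain CellPhenotypeParams objects")
  if (object@nPerClass < 1L) msg <- c(msg, "nPerClass must be >= 1")
  if (object@imageSize < 16L) msg <- c(msg, "imageSize must be >= 16")
  if (object@separationDelta < 0) msg <- c(msg, "separationDelta must be >= 0")
  for (nm in names(object@classParams)) {
    p <- object@classParams[[nm]]
    if (is(p, "CellPhenotypeParams")) {
      # semi-major axis at mean + 2 sd must keep a 2-pixel margin
      r <- p@cellRadiusMean + 2 * p@cellRadiusSd
      a <- r / (1 - min(p@eccentricityMean + 2 * p@eccentricitySd, 0.95)^2)^0.25
      if (a > object@imageSize / 2 - 2)
        msg <- c(msg, sprintf("class '%s': cell does not fit the canvas with a 2-pixel margin", nm))
    }
  }
  if (length(msg)) msg else TRUE
})
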
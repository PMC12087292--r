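# stratified splitting, fine-tuning, prediction

#' Split a datastore into train/validation/test folds
#'
#' Partitions the records into disjoint folds whose union is the input. With
#' stratification (default), the split is performed within each class: the
#' validation and test folds receive \code{floor(fraction * n)} records and
#' the remainder goes to training, so per-class proportions deviate by at
#' most one image. Deterministic given the seed.
#'
#' @param ds a \code{\link{CellImageSet}}.
#' @param spec a \code{\link{SplitSpec}} (default 0.6:0.2:0.2, stratified).
#' @return Named list of three \code{CellImageSet}s: \code{train},
#'   \code{validate}, \code{test}, all sharing the input's class universe.
#' @examples
#' \donttest{
#' ds <- synthesizeDatastore(syntheticSpec(2, nPerClass = 10, imageSize = 32))
#' folds <- splitDataset(ds, SplitSpec(seed = 1))
#' vapply(folds, length, integer(1))  # 12 / 4 / 4
#' }
#' @export
splitDataset <- function(ds, spec = SplitSpec()) {
  stopifnot(is(ds, "CellImageSet"), is(spec, "SplitSpec"))
  validObject(spec)
  fr <- c(train = spec@trainFraction, validate = spec@validateFraction,
          test = spec@testFraction)
  set.seed(spec@seed)
  idx <- list(train = integer(0), validate = integer(0), test = integer(0))
  groups <- if (spec@stratified) {
    split(seq_len(length(ds)), factor(imageLabels(ds), levels = classNames(ds)))
  } else {
    list(all = seq_len(length(ds)))
  }
  for (g in names(groups)) {
    ix <- groups[[g]]
    n <- length(ix)
    if (n == 0L) next
    nVal <- floor(fr[["validate"]] * n)
    nTest <- floor(fr[["test"]] * n)
    nTrain <- n - nVal - nTest
    for (fold in names(fr)) {
      want <- switch(fold, train = nTrain, validate = nVal, test = nTest)
      if (fr[[fold]] > 0 && want == 0L)
        stop(sprintf("class '%s' (%d images) is too small to populate the non-empty '%s' fold",
                     g, n, fold))
    }
    ix <- ix[sample.int(n)]
    idx$validate <- c(idx$validate, ix[seq_len(nVal)])
    idx$test <- c(idx$test, ix[nVal + seq_len(nTest)])
    idx$train <- c(idx$train, ix[nVal + nTest + seq_len(nTrain)])
  }
  lapply(idx, function(i) ds[sort(i)])
}

#' Fine-tune a backbone on a labeled datastore
#'
#' Transfer-learning style fine-tuning: images are bilinearly resized to the
#' backbone's input size (grayscale replicated to 3 channels), passed through
#' the frozen convolutional trunk once to cache features, and the dense
#' block + softmax classification head on top are optimised by mini-batch
#' SGDM/Adam/RMSProp with early stopping. The classification layer emits one
#' score per class of the training universe. The retained weights are those
#' of the epoch with the best validation accuracy. Reproducible given
#' \code{cfg@seed}.
#'
#' The backbone's \code{frozenDepth} decides how much of the network trains:
#' at or below the trunk boundary the dense block and head both train (the
#' default, standard for small datasets); above it only the head trains.
#' Convolutional stages themselves always stay frozen in this implementation.
#'
#' @param train,validate \code{\link{CellImageSet}} folds sharing a class
#'   universe; every validation label must occur in training.
#' @param backbone a \code{\link{BackboneSpec}}.
#' @param cfg a \code{\link{TrainConfig}}.
#' @param trunk optional pretrained trunk weights (list of W/b layers) for
#'   artifact-backed backbones; surrogates materialise their own.
#' @return A \code{\link{FineTunedModel}}.
#' @export
fineTuneBackbone <- function(train, validate, backbone, cfg = TrainConfig(),
                             trunk = NULL) {
  stopifnot(is(train, "CellImageSet"), is(validate, "CellImageSet"),
            is(backbone, "BackboneSpec"), is(cfg, "TrainConfig"))
  validObject(cfg); validObject(backbone)
  if (length(train) == 0L) stop("training fold is empty")
  cls <- classNames(train)
  extra <- setdiff(unique(imageLabels(validate)), unique(imageLabels(train)))
  if (length(extra))
    stop("label(s) present in validation but absent from training: ",
         paste(extra, collapse = ", "))
  trunk <- trunk %||% .materializeTrunk(backbone)
  nConv <- length(trunk)
  nLayers <- nConv + 2L
  nFrozen <- round(backbone@frozenDepth * nLayers)
  trainDense <- nFrozen <= nConv
  if (nFrozen < nConv)
    warning("frozenDepth requests unfreezing convolutional stages; the trunk remains frozen and the dense block + head are trained")
  Xtr <- .extractFeatures(train, trunk, backbone@inputSize)
  Xva <- .extractFeatures(validate, trunk, backbone@inputSize)
  mu <- colMeans(Xtr)
  sdv <- pmax(apply(Xtr, 2L, sd), 1e-6)
  Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/")
  if (nrow(Xva)) Xva <- sweep(sweep(Xva, 2L, mu), 2L, sdv, "/")
  ytr <- match(imageLabels(train), cls)
  yva <- match(imageLabels(validate), cls)
  fit <- .trainHead(Xtr, ytr, Xva, yva, K = length(cls),
                    hidden = backbone@hiddenUnits, cfg = cfg,
                    trainDense = trainDense)
  new("FineTunedModel", backbone = backbone, classNames = cls,
      trunk = trunk, dense = fit$par, featNorm = list(mu = mu, sd = sdv),
      trainingLog = fit$log, trainConfig = cfg,
      bestEpoch = as.integer(fit$bestEpoch))
}

#' Predict class labels and scores for a datastore
#'
#' Applies a fine-tuned model to every record: the predicted label is the
#' argmax of the class scores; the score vector is softmax-normalised
#' (non-negative, sums to 1). Output order matches the datastore.
#'
#' @param object a \code{\link{FineTunedModel}}.
#' @param ds a \code{\link{CellImageSet}} (its class universe must not
#'   extend beyond the model's).
#' @param ... ignored.
#' @return A \code{\link{PredictionSet}}.
#' @importFrom stats predict
#' @export
setMethod("predict", "FineTunedModel", function(object, ds, ...) {
  stopifnot(is(ds, "CellImageSet"))
  if (length(ds) == 0L) {
    return(new("PredictionSet", recordIds = character(0),
               predictedLabels = character(0),
               scores = matrix(0, 0L, length(object@classNames)),
               classNames = object@classNames,
               modelId = object@backbone@name))
  }
  X <- .extractFeatures(ds, object@trunk, object@backbone@inputSize)
  X <- sweep(sweep(X, 2L, object@featNorm$mu), 2L, object@featNorm$sd, "/")
  P <- .denseForward(X, object@dense)$P
  colnames(P) <- object@classNames
  new("PredictionSet", recordIds = sourcePaths(ds),
      predictedLabels = object@classNames[max.col(P, ties.method = "first")],
      scores = P, classNames = object@classNames,
      modelId = object@backbone@name)
})

#' Save / load a fine-tuned model
#'
#' The weights (trunk, dense block, feature normalisation) are serialised to
#' \code{<path>.rds}; a JSON sidecar \code{<path>.json} records the backbone
#' name, class names, training configuration and best epoch, and the
#' training log is written to \code{<path>_log.csv}.
#'
#' @param model a \code{\link{FineTunedModel}}.
#' @param path file stem (no extension).
#' @return \code{saveModel}: the stem, invisibly. \code{loadModel}: the
#'   restored \code{FineTunedModel}.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "FineTunedModel"))
  saveRDS(list(trunk = model@trunk, dense = model@dense,
               featNorm = model@featNorm), paste0(path, ".rds"))
  cfg <- model@trainConfig
  side <- list(backbone = list(name = model@backbone@name,
                               inputSize = model@backbone@inputSize,
                               pretrainedSource = model@backbone@pretrainedSource,
                               frozenDepth = model@backbone@frozenDepth,
                               convFilters = model@backbone@convFilters,
                               hiddenUnits = model@backbone@hiddenUnits,
                               weightSeed = model@backbone@weightSeed),
               classNames = model@classNames,
               trainConfig = list(optimizer = cfg@optimizer,
                                  learningRate = cfg@learningRate,
                                  maxEpochs = cfg@maxEpochs,
                                  miniBatchSize = cfg@miniBatchSize,
                                  seed = cfg@seed,
                                  earlyStoppingPatience = cfg@earlyStoppingPatience,
                                  classWeighting = cfg@classWeighting),
               bestEpoch = model@bestEpoch)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write.csv(model@trainingLog, paste0(path, "_log.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  wts <- readRDS(paste0(path, ".rds"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  bb <- new("BackboneSpec", name = side$backbone$name,
            inputSize = as.integer(side$backbone$inputSize),
            pretrainedSource = side$backbone$pretrainedSource,
            frozenDepth = side$backbone$frozenDepth,
            convFilters = as.integer(side$backbone$convFilters),
            hiddenUnits = as.integer(side$backbone$hiddenUnits),
            weightSeed = as.integer(side$backbone$weightSeed))
  tc <- side$trainConfig
  cfg <- TrainConfig(optimizer = tc$optimizer, learningRate = tc$learningRate,
                     maxEpochs = tc$maxEpochs,
                     miniBatchSize = tc$miniBatchSize, seed = tc$seed,
                     earlyStoppingPatience = tc$earlyStoppingPatience,
                     classWeighting = tc$classWeighting)
  log <- read.csv(paste0(path, "_log.csv"))
  new("FineTunedModel", backbone = bb, classNames = side$classNames,
      trunk = wts$trunk, dense = wts$dense, featNorm = wts$featNorm,
      trainingLog = log, trainConfig = cfg,
      bestEpoch = as.integer(side$bestEpoch))
}
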
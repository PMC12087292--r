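# confusion charts, accuracy statistics, experiment drivers

#' Cross-tabulate true versus predicted classes
#'
#' Builds the confusion chart: \code{counts[i, j]} is the number of records
#' of true class i predicted as class j. When both arguments carry record
#' identifiers they must be aligned one-to-one.
#'
#' @param truth a \code{\link{CellImageSet}} (labels + class universe) or a
#'   character vector of true labels.
#' @param pred a \code{\link{PredictionSet}}, \code{\link{EnsemblePrediction}}
#'   or character vector of predicted labels.
#' @param classLevels optional explicit class universe; defaults to the
#'   universe carried by \code{truth} (or the sorted union of labels).
#' @return A \code{\link{ConfusionChart}}.
#' @examples
#' chart <- confusionChart(c("A", "A", "B"), c("A", "B", "B"))
#' chartCounts(chart)
#' @export
confusionChart <- function(truth, pred, classLevels = NULL) {
  if (is(truth, "CellImageSet")) {
    classLevels <- classLevels %||% classNames(truth)
    truthIds <- sourcePaths(truth)
    truth <- imageLabels(truth)
  } else truthIds <- NULL
  if (is(pred, "PredictionSet") || is(pred, "EnsemblePrediction")) {
    predIds <- pred@recordIds
    classLevels <- classLevels %||% classNames(pred)
    pred <- predictedLabels(pred)
  } else predIds <- NULL
  if (length(truth) == 0L) stop("empty evaluation input")
  if (length(truth) != length(pred))
    stop("truth and predictions have different lengths")
  if (!is.null(truthIds) && !is.null(predIds) && !identical(truthIds, predIds))
    stop("truth and prediction records are not aligned")
  classLevels <- classLevels %||% sort(unique(c(truth, pred)))
  counts <- unclass(table(factor(truth, levels = classLevels),
                          factor(pred, levels = classLevels)))
  dimnames(counts) <- list(true = classLevels, predicted = classLevels)
  new("ConfusionChart", classNames = classLevels,
      counts = matrix(as.integer(counts), nrow(counts),
                      dimnames = dimnames(counts)))
}

#' @describeIn ConfusionChart-class overall accuracy,
#'   \code{100 * trace / total} percent.
#' @export
setMethod("overallAccuracy", "ConfusionChart", function(x) {
  tot <- sum(x@counts)
  if (tot == 0L) stop("empty confusion chart")
  100 * sum(diag(x@counts)) / tot
})

#' @describeIn ConfusionChart-class per-class accuracy (percent; NA for
#'   absent classes).
#' @export
setMethod("perClassAccuracy", "ConfusionChart", function(x) {
  sup <- rowSums(x@counts)
  acc <- ifelse(sup > 0, 100 * diag(x@counts) / sup, NA_real_)
  names(acc) <- x@classNames
  acc
})

#' @describeIn ConfusionChart-class macro-averaged accuracy (percent).
#' @export
setMethod("balancedAccuracy", "ConfusionChart", function(x) {
  mean(perClassAccuracy(x), na.rm = TRUE)
})

#' @describeIn ExperimentReport-class ensemble overall test accuracy (%).
#' @param x an \code{ExperimentReport}.
#' @export
setMethod("overallAccuracy", "ExperimentReport", function(x) x@ensembleAccuracy)

# relabel every record of a datastore to a single class name
.relabel <- function(ds, label) {
  new("CellImageSet", images = ds@images,
      labels = rep(label, length(ds)), sourcePaths = ds@sourcePaths,
      classNames = label)
}

.trainConfigList <- function(cfg) {
  list(optimizer = cfg@optimizer, learningRate = cfg@learningRate,
       maxEpochs = cfg@maxEpochs, miniBatchSize = cfg@miniBatchSize,
       seed = cfg@seed, earlyStoppingPatience = cfg@earlyStoppingPatience,
       classWeighting = cfg@classWeighting)
}

#' Run a multi-class classification experiment
#'
#' The full protocol applied to one labeled datastore: stratified
#' train/validation/test split, independent fine-tuning of every backbone,
#' per-model evaluation on the held-out test fold, plurality-vote fusion,
#' and a report with a full configuration snapshot. Accuracy is computed on
#' the test fold only — images unseen during training — with the validation
#' fold used solely for epoch selection.
#'
#' @param ds a labeled \code{\link{CellImageSet}}.
#' @param backbones list of \code{\link{BackboneSpec}}s (or registry names).
#' @param split a \code{\link{SplitSpec}}.
#' @param cfg a \code{\link{TrainConfig}}.
#' @param name experiment label.
#' @param notes optional character annotations.
#' @return An \code{\link{ExperimentReport}}. The trained models and the
#'   ensemble prediction are attached as attributes \code{"models"} and
#'   \code{"ensemblePrediction"}.
#' @export
runClassificationExperiment <- function(ds, backbones, split = SplitSpec(),
                                        cfg = TrainConfig(),
                                        name = "experiment",
                                        notes = character(0)) {
  if (is.character(backbones)) backbones <- lapply(backbones, getBackbone)
  stopifnot(length(backbones) >= 1L)
  folds <- splitDataset(ds, split)
  models <- lapply(backbones, function(bb)
    fineTuneBackbone(folds$train, folds$validate, bb, cfg))
  preds <- lapply(models, predict, ds = folds$test)
  singleAcc <- vapply(preds, function(p)
    overallAccuracy(confusionChart(folds$test, p)), numeric(1))
  names(singleAcc) <- vapply(backbones, function(b) b@name, character(1))
  ens <- majorityVote(tallyVotes(preds), preds)
  chart <- confusionChart(folds$test, ens)
  config <- list(split = list(train = split@trainFraction,
                              validate = split@validateFraction,
                              test = split@testFraction,
                              stratified = split@stratified,
                              seed = split@seed),
                 trainConfig = .trainConfigList(cfg),
                 backbones = names(singleAcc),
                 classNames = classNames(ds),
                 nTrain = length(folds$train),
                 nValidate = length(folds$validate),
                 nTest = length(folds$test))
  config$hash <- .hashObject(config)
  report <- new("ExperimentReport", name = name,
                modelAccuracies = singleAcc,
                ensembleAccuracy = overallAccuracy(chart),
                perClassAccuracy = perClassAccuracy(chart),
                balancedAccuracy = balancedAccuracy(chart),
                chart = chart, config = config, notes = notes)
  attr(report, "models") <- models
  attr(report, "ensemblePrediction") <- ens
  report
}

#' Run a binary classification experiment
#'
#' Merges two datastores under two labels, then runs the standard protocol
#' (split, per-backbone fine-tuning, test-fold evaluation singly and as an
#' ensemble).
#'
#' @param dsPos,dsNeg non-empty \code{\link{CellImageSet}}s for the two
#'   groups.
#' @param backbones list of \code{\link{BackboneSpec}}s or registry names.
#' @param split a \code{\link{SplitSpec}}.
#' @param cfg a \code{\link{TrainConfig}}.
#' @param labels length-2 character: names for the positive and negative
#'   group.
#' @param name experiment label.
#' @return An \code{\link{ExperimentReport}}.
#' @export
runBinaryExperiment <- function(dsPos, dsNeg, backbones, split = SplitSpec(),
                                cfg = TrainConfig(),
                                labels = c("positive", "negative"),
                                name = "binary") {
  if (length(dsPos) == 0L || length(dsNeg) == 0L)
    stop("both datastores must be non-empty")
  merged <- c(.relabel(dsPos, labels[1L]), .relabel(dsNeg, labels[2L]))
  runClassificationExperiment(merged, backbones, split, cfg, name = name)
}

#' Run a one-vs-rest identification experiment
#'
#' Relabels every class other than \code{targetClass} as a single pooled
#' \code{restLabel} class and runs the binary protocol. The class imbalance
#' ratio is recorded in the report notes, and balanced accuracy is always
#' reported alongside plain accuracy since pooled-rest designs are typically
#' imbalanced.
#'
#' @param targetClass the class to identify.
#' @param dsAll labeled \code{\link{CellImageSet}} containing
#'   \code{targetClass} and at least one other class.
#' @param backbones list of \code{\link{BackboneSpec}}s or registry names.
#' @param split a \code{\link{SplitSpec}}.
#' @param cfg a \code{\link{TrainConfig}}.
#' @param restLabel label for the pooled remainder.
#' @param name experiment label.
#' @return An \code{\link{ExperimentReport}}.
#' @export
runOneVsRestExperiment <- function(targetClass, dsAll, backbones,
                                   split = SplitSpec(), cfg = TrainConfig(),
                                   restLabel = "rest",
                                   name = paste0(targetClass, "_vs_rest")) {
  labs <- imageLabels(dsAll)
  if (!targetClass %in% labs) stop("target class '", targetClass,
                                   "' absent from the datastore")
  if (all(labs == targetClass)) stop("no other class to pool into the rest")
  newLabs <- ifelse(labs == targetClass, targetClass, restLabel)
  merged <- new("CellImageSet", images = dsAll@images, labels = newLabs,
                sourcePaths = dsAll@sourcePaths,
                classNames = sort(c(targetClass, restLabel)))
  ratio <- sum(newLabs != targetClass) / sum(newLabs == targetClass)
  runClassificationExperiment(merged, backbones, split, cfg, name = name,
    notes = sprintf("one-vs-rest imbalance %s:rest = 1:%.2f", targetClass, ratio))
}

#' Compare single-model and ensemble accuracy
#'
#' Descriptive comparison table for a report: each model's test accuracy,
#' the min/median/max over single models, the ensemble accuracy and the
#' ensemble-minus-median-single delta. No significance test is attached.
#'
#' @param report an \code{\link{ExperimentReport}} with at least two models.
#' @return A list with \code{models} (data.frame model/accuracy) and
#'   \code{summary} (data.frame with minSingle, medianSingle, maxSingle,
#'   ensemble, deltaVsMedian).
#' @export
compareSingleVsEnsemble <- function(report) {
  stopifnot(is(report, "ExperimentReport"))
  acc <- report@modelAccuracies
  if (length(acc) < 2L)
    stop("comparison requires at least two single-model accuracies")
  list(models = data.frame(model = names(acc), accuracy = unname(acc),
                           stringsAsFactors = FALSE),
       summary = data.frame(minSingle = min(acc),
                            medianSingle = median(acc),
                            maxSingle = max(acc),
                            ensemble = report@ensembleAccuracy,
                            deltaVsMedian = report@ensembleAccuracy - median(acc)))
}
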
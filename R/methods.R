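# accessors, subsetting, combination and show methods

#' @describeIn CellImageSet-class number of records.
#' @param x a \code{CellImageSet}.
#' @export
setMethod("length", "CellImageSet", function(x) length(x@images))

#' @describeIn CellImageSet-class class-label universe.
#' @export
setMethod("classNames", "CellImageSet", function(x) x@classNames)

#' @describeIn CellImageSet-class per-record class labels.
#' @export
setMethod("imageLabels", "CellImageSet", function(x) x@labels)

#' @describeIn CellImageSet-class per-record provenance paths.
#' @export
setMethod("sourcePaths", "CellImageSet", function(x) x@sourcePaths)

#' @describeIn CellImageSet-class list of image arrays.
#' @export
setMethod("images", "CellImageSet", function(x) x@images)

#' @describeIn CellImageSet-class subset records, keeping the class universe.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "CellImageSet", function(x, i, j, ..., drop = FALSE) {
  new("CellImageSet", images = x@images[i], labels = x@labels[i],
      sourcePaths = x@sourcePaths[i], classNames = x@classNames)
})

#' Combine datastores
#'
#' Pools records from several datastores (e.g. image trees scanned from
#' different sources); the class universe is the sorted union.
#'
#' @param x,... \code{CellImageSet} objects.
#' @return A pooled \code{CellImageSet}.
#' @export
setMethod("c", "CellImageSet", function(x, ...) {
  sets <- c(list(x), list(...))
  new("CellImageSet",
      images = do.call(c, lapply(sets, function(s) s@images)),
      labels = do.call(c, lapply(sets, function(s) s@labels)),
      sourcePaths = do.call(c, lapply(sets, function(s) s@sourcePaths)),
      classNames = sort(unique(do.call(c, lapply(sets, function(s) s@classNames)))))
})

setMethod("show", "CellImageSet", function(object) {
  cat(sprintf("CellImageSet with %d record(s) over %d class(es)\n",
              length(object@images), length(object@classNames)))
  tab <- table(factor(object@labels, levels = object@classNames))
  for (nm in names(tab)) cat(sprintf("  %-24s %d\n", nm, tab[[nm]]))
})

#' @describeIn PreprocessConfig-class grayscale channel weights.
#' @param x a \code{PreprocessConfig}.
#' @export
setMethod("grayCoefficients", "PreprocessConfig", function(x) x@grayCoefficients)

setMethod("show", "PreprocessConfig", function(object) {
  cat(sprintf("PreprocessConfig: gray = %.3f R + %.3f G + %.3f B; stretch %g-%g%%\n",
              object@grayCoefficients[1], object@grayCoefficients[2],
              object@grayCoefficients[3], object@lowerPercentile,
              object@upperPercentile))
})

#' @describeIn PredictionSet-class number of predicted records.
#' @param x a \code{PredictionSet}.
#' @export
setMethod("length", "PredictionSet", function(x) length(x@recordIds))

#' @describeIn PredictionSet-class predicted (argmax) labels.
#' @export
setMethod("predictedLabels", "PredictionSet", function(x) x@predictedLabels)

#' @describeIn PredictionSet-class normalised score matrix.
#' @export
setMethod("scores", "PredictionSet", function(x) x@scores)

#' @describeIn PredictionSet-class class universe.
#' @export
setMethod("classNames", "PredictionSet", function(x) x@classNames)

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet '%s': %d record(s), %d class(es)\n",
              object@modelId, length(object@recordIds),
              length(object@classNames)))
})

#' @describeIn VoteTally-class per-record vote-count matrix.
#' @param x a \code{VoteTally}.
#' @export
setMethod("votes", "VoteTally", function(x) x@counts)

#' @describeIn VoteTally-class class universe.
#' @export
setMethod("classNames", "VoteTally", function(x) x@classNames)

#' @describeIn VoteTally-class number of records tallied.
#' @export
setMethod("length", "VoteTally", function(x) length(x@recordIds))

setMethod("show", "VoteTally", function(object) {
  cat(sprintf("VoteTally: %d record(s), %d model(s), %d class(es)\n",
              length(object@recordIds), object@nModels,
              length(object@classNames)))
})

#' @describeIn EnsemblePrediction-class fused winning labels.
#' @param x an \code{EnsemblePrediction}.
#' @export
setMethod("predictedLabels", "EnsemblePrediction", function(x) x@predictedLabels)

#' @describeIn EnsemblePrediction-class mean score matrix across models.
#' @export
setMethod("scores", "EnsemblePrediction", function(x) x@meanScores)

#' @describeIn EnsemblePrediction-class which records needed tie-breaking.
#' @export
setMethod("tieBroken", "EnsemblePrediction", function(x) x@tieBroken)

#' @describeIn EnsemblePrediction-class class universe.
#' @export
setMethod("classNames", "EnsemblePrediction", function(x) x@classNames)

#' @describeIn EnsemblePrediction-class number of records.
#' @export
setMethod("length", "EnsemblePrediction", function(x) length(x@recordIds))

setMethod("show", "EnsemblePrediction", function(object) {
  cat(sprintf("EnsemblePrediction: %d record(s) fused from %d model(s); %d tie(s) broken\n",
              length(object@recordIds), object@nModels,
              sum(object@tieBroken)))
})

#' @describeIn ConfusionChart-class true-by-predicted count matrix.
#' @param x a \code{ConfusionChart}.
#' @export
setMethod("chartCounts", "ConfusionChart", function(x) x@counts)

#' @describeIn ConfusionChart-class per-class totals (row sums).
#' @export
setMethod("classSupport", "ConfusionChart", function(x) {
  structure(rowSums(x@counts), names = x@classNames)
})

#' @describeIn ConfusionChart-class class universe.
#' @export
setMethod("classNames", "ConfusionChart", function(x) x@classNames)

setMethod("show", "ConfusionChart", function(object) {
  cat(sprintf("ConfusionChart over %d class(es), %d record(s), accuracy %.1f%%\n",
              length(object@classNames), sum(object@counts),
              overallAccuracy(object)))
  print(object@counts)
})

#' @describeIn FineTunedModel-class class universe the model predicts over.
#' @param x a \code{FineTunedModel}.
#' @export
setMethod("classNames", "FineTunedModel", function(x) x@classNames)

#' @describeIn FineTunedModel-class per-epoch training log.
#' @export
setMethod("trainingLog", "FineTunedModel", function(x) x@trainingLog)

setMethod("show", "FineTunedModel", function(object) {
  log <- object@trainingLog
  cat(sprintf("FineTunedModel '%s': %d class(es), %d epoch(s), best epoch %d (val acc %.3f)\n",
              object@backbone@name, length(object@classNames), nrow(log),
              object@bestEpoch, log$val_accuracy[object@bestEpoch]))
})

setMethod("show", "BackboneSpec", function(object) {
  arch <- if (length(object@convFilters))
    paste0("trunk [", paste(object@convFilters, collapse = "-"),
           "] + dense ", object@hiddenUnits)
  else "artifact-backed trunk"
  cat(sprintf("BackboneSpec '%s': input %dx%d, %s, %s, frozenDepth %.2f\n",
              object@name, object@inputSize, object@inputSize, arch,
              object@pretrainedSource, object@frozenDepth))
})

setMethod("show", "ExperimentReport", function(object) {
  cat(sprintf("ExperimentReport '%s'\n", object@name))
  cat(sprintf("  models: %d, single accuracies %.1f-%.1f%% (median %.1f%%)\n",
              length(object@modelAccuracies), min(object@modelAccuracies),
              max(object@modelAccuracies), median(object@modelAccuracies)))
  cat(sprintf("  ensemble accuracy: %.1f%% (balanced %.1f%%)\n",
              object@ensembleAccuracy, object@balancedAccuracy))
  if (length(object@notes)) cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})

setMethod("show", "SyntheticDatasetSpec", function(object) {
  cat(sprintf("SyntheticDatasetSpec: %d class(es) x %d image(s), %dpx canvas, delta %.3g, seed %d\n",
              length(object@classParams), object@nPerClass, object@imageSize,
              object@separationDelta, object@seed))
})
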
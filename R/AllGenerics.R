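#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @export
setGeneric("imageLabels", function(x) standardGeneric("imageLabels"))

#' @export
setGeneric("sourcePaths", function(x) standardGeneric("sourcePaths"))

#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' @export
setGeneric("predictedLabels", function(x) standardGeneric("predictedLabels"))

#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @export
setGeneric("votes", function(x) standardGeneric("votes"))

#' @export
setGeneric("tieBroken", function(x) standardGeneric("tieBroken"))

#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))

#' @export
setGeneric("chartCounts", function(x) standardGeneric("chartCounts"))

#' @export
setGeneric("classSupport", function(x) standardGeneric("classSupport"))

#' @export
setGeneric("grayCoefficients", function(x) standardGeneric("grayCoefficients"))

#' Overall classification accuracy of a confusion chart
#'
#' @param x a \code{ConfusionChart} (or \code{ExperimentReport}).
#' @return Overall accuracy in percent: \code{100 * trace / total}.
#' @export
setGeneric("overallAccuracy", function(x) standardGeneric("overallAccuracy"))

#' Per-class accuracy of a confusion chart
#'
#' @param x a \code{ConfusionChart}.
#' @return Named numeric vector of per-class accuracies in percent
#'   (\code{NA} for classes with zero support).
#' @export
setGeneric("perClassAccuracy", function(x) standardGeneric("perClassAccuracy"))

#' Balanced (macro-averaged) accuracy of a confusion chart
#'
#' Mean of per-class accuracies; informative when classes are imbalanced and
#' plain overall accuracy is optimistic.
#'
#' @param x a \code{ConfusionChart}.
#' @return Balanced accuracy in percent.
#' @export
setGeneric("balancedAccuracy", function(x) standardGeneric("balancedAccuracy"))
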
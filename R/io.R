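# persistence of predictions, charts and reports

#' Write / read predictions as CSV
#'
#' Round-trips a \code{\link{PredictionSet}} through a flat CSV (record id,
#' model id, predicted label, one score column per class), so predictions
#' from external classifiers can be fused by the same voting engine.
#'
#' @param ps a \code{\link{PredictionSet}}.
#' @param file CSV path.
#' @return \code{writePredictions}: the path, invisibly.
#'   \code{readPredictions}: the restored \code{PredictionSet}.
#' @export
writePredictions <- function(ps, file) {
  stopifnot(is(ps, "PredictionSet"))
  df <- data.frame(record_id = ps@recordIds, model_id = ps@modelId,
                   predicted_label = ps@predictedLabels,
                   stringsAsFactors = FALSE)
  sc <- as.data.frame(ps@scores)
  names(sc) <- paste0("score.", ps@classNames)
  write.csv(cbind(df, sc), file, row.names = FALSE)
  invisible(file)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  scoreCols <- grep("^score\\.", names(df), value = TRUE)
  cls <- sub("^score\\.", "", scoreCols)
  sc <- as.matrix(df[, scoreCols, drop = FALSE])
  colnames(sc) <- cls
  new("PredictionSet", recordIds = as.character(df$record_id),
      predictedLabels = as.character(df$predicted_label), scores = sc,
      classNames = cls, modelId = as.character(df$model_id[1] %||% "external"))
}

#' Write a confusion chart as a CSV grid
#'
#' @param chart a \code{\link{ConfusionChart}}.
#' @param file CSV path; rows are true classes, columns predicted classes.
#' @return The path, invisibly.
#' @export
writeConfusionCSV <- function(chart, file) {
  stopifnot(is(chart, "ConfusionChart"))
  df <- as.data.frame(chart@counts)
  names(df) <- chart@classNames
  df <- cbind(true_class = chart@classNames, df)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Serialise an experiment report
#'
#' Writes the report as JSON (accuracies, per-class accuracy, confusion
#' counts, configuration snapshot with hash, notes). The rendering is fully
#' deterministic — no timestamps — so identically configured runs produce
#' byte-identical files.
#'
#' @param report an \code{\link{ExperimentReport}}.
#' @param file JSON path.
#' @return The path, invisibly.
#' @export
writeReport <- function(report, file) {
  stopifnot(is(report, "ExperimentReport"))
  out <- list(name = report@name,
              modelAccuracies = as.list(report@modelAccuracies),
              ensembleAccuracy = report@ensembleAccuracy,
              perClassAccuracy = as.list(report@perClassAccuracy),
              balancedAccuracy = report@balancedAccuracy,
              confusion = list(classNames = report@chart@classNames,
                               counts = report@chart@counts),
              config = report@config,
              notes = report@notes)
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Render a confusion chart heatmap
#'
#' Side output only — never an input to any computation.
#'
#' @param chart a \code{\link{ConfusionChart}}.
#' @param main plot title.
#' @return NULL, invisibly.
#' @importFrom graphics axis image text
#' @importFrom grDevices hcl.colors
#' @export
plotConfusionChart <- function(chart, main = "Confusion chart") {
  stopifnot(is(chart, "ConfusionChart"))
  k <- length(chart@classNames)
  m <- chart@counts[k:1, , drop = FALSE]  # truth top-to-bottom
  image(seq_len(k), seq_len(k), t(m), col = hcl.colors(64, "Blues 3",
                                                       rev = TRUE),
        axes = FALSE, xlab = "Predicted class", ylab = "True class",
        main = main)
  axis(1, at = seq_len(k), labels = chart@classNames, las = 2, cex.axis = 0.8)
  axis(2, at = seq_len(k), labels = rev(chart@classNames), las = 2,
       cex.axis = 0.8)
  for (i in seq_len(k)) for (j in seq_len(k))
    text(j, i, m[i, j], cex = 0.8)
  invisible(NULL)
}

#' Bar chart of single-model versus ensemble accuracy
#'
#' Side output only.
#'
#' @param report an \code{\link{ExperimentReport}}.
#' @return NULL, invisibly.
#' @importFrom graphics abline barplot legend
#' @export
plotAccuracyComparison <- function(report) {
  stopifnot(is(report, "ExperimentReport"))
  acc <- report@modelAccuracies
  bp <- barplot(acc, ylim = c(0, 100), ylab = "Test accuracy (%)",
                las = 2, col = "grey70",
                main = sprintf("%s: single models vs ensemble", report@name))
  abline(h = report@ensembleAccuracy, col = "firebrick", lwd = 2, lty = 2)
  legend("bottomright", legend = sprintf("ensemble %.1f%%",
                                         report@ensembleAccuracy),
         lty = 2, lwd = 2, col = "firebrick", bty = "n")
  invisible(NULL)
}
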
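# plurality ("majority rule") fusion of independent model predictions

#' Tally votes across models
#'
#' Counts, per record, how many models predicted each class. All prediction
#' sets must cover identical records (same order) and the same class
#' universe; each model contributes exactly one vote per record, unweighted,
#' so per-record counts always sum to the number of models.
#'
#' @param predictions list of \code{\link{PredictionSet}}s.
#' @return A \code{\link{VoteTally}}.
#' @export
tallyVotes <- function(predictions) {
  if (!is.list(predictions) || length(predictions) == 0L)
    stop("predictions must be a non-empty list of PredictionSet objects")
  stopifnot(all(vapply(predictions, is, logical(1), "PredictionSet")))
  ref <- predictions[[1L]]
  for (ps in predictions[-1L]) {
    if (!identical(ps@recordIds, ref@recordIds)) {
      diff <- union(setdiff(ps@recordIds, ref@recordIds),
                    setdiff(ref@recordIds, ps@recordIds))
      stop("prediction sets cover different records: ",
           paste(head(c(diff, if (!length(diff)) "(same records, different order)"), 5L),
                 collapse = ", "))
    }
    if (!identical(ps@classNames, ref@classNames))
      stop("prediction sets use different class universes: ",
           paste(union(setdiff(ps@classNames, ref@classNames),
                       setdiff(ref@classNames, ps@classNames)), collapse = ", "))
  }
  k <- length(ref@classNames)
  counts <- matrix(0L, length(ref@recordIds), k,
                   dimnames = list(NULL, ref@classNames))
  for (ps in predictions) {
    j <- match(ps@predictedLabels, ref@classNames)
    for (col in seq_len(k)) counts[, col] <- counts[, col] + (j == col)
  }
  new("VoteTally", recordIds = ref@recordIds, counts = counts,
      classNames = ref@classNames, nModels = length(predictions))
}

#' Fuse a vote tally into an ensemble prediction by majority rule
#'
#' The winner of each record is the class with the maximum number of votes
#' (plurality; an absolute majority is not required). Ties among classes
#' sharing the maximum are broken by the highest mean normalised score
#' across models, then lexicographically by class name; tie-broken records
#' are flagged.
#'
#' @param tally a \code{\link{VoteTally}}.
#' @param predictions the list of \code{\link{PredictionSet}}s the tally was
#'   computed from (supplies the mean scores for tie-breaking).
#' @return An \code{\link{EnsemblePrediction}}.
#' @export
majorityVote <- function(tally, predictions) {
  stopifnot(is(tally, "VoteTally"))
  n <- length(tally@recordIds)
  if (n == 0L) stop("empty tally")
  if (length(predictions) != tally@nModels ||
      !identical(predictions[[1L]]@recordIds, tally@recordIds))
    stop("tally is not consistent with the supplied predictions")
  meanScores <- Reduce(`+`, lapply(predictions, scores)) / tally@nModels
  colnames(meanScores) <- tally@classNames
  labels <- character(n)
  winning <- integer(n)
  tie <- logical(n)
  for (i in seq_len(n)) {
    cnt <- tally@counts[i, ]
    mx <- max(cnt)
    cand <- which(cnt == mx)
    tie[i] <- length(cand) > 1L
    if (tie[i]) {
      ms <- meanScores[i, cand]
      cand <- cand[ms == max(ms)]
      if (length(cand) > 1L)
        cand <- cand[order(tally@classNames[cand])[1L]]
    }
    labels[i] <- tally@classNames[cand[1L]]
    winning[i] <- as.integer(mx)
  }
  new("EnsemblePrediction", recordIds = tally@recordIds,
      predictedLabels = labels, winningCounts = winning, tieBroken = tie,
      meanScores = meanScores, classNames = tally@classNames,
      nModels = tally@nModels)
}

#' Predict with an ensemble of fine-tuned models
#'
#' Runs every model independently over the datastore, tallies the predicted
#' labels and fuses them by plurality voting. The models are never merged
#' architecturally — each remains an independent voter.
#'
#' @param models list of \code{\link{FineTunedModel}}s sharing a class
#'   universe.
#' @param ds a non-empty \code{\link{CellImageSet}}.
#' @return An \code{\link{EnsemblePrediction}}.
#' @export
ensemblePredict <- function(models, ds) {
  stopifnot(is.list(models), length(models) >= 1L,
            all(vapply(models, is, logical(1), "FineTunedModel")))
  if (length(ds) == 0L) stop("ds must be non-empty")
  preds <- lapply(models, predict, ds = ds)
  majorityVote(tallyVotes(preds), preds)
}
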
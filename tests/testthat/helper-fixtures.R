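# shared fixtures: tiny datastores, fabricated predictions, vote oracle

# a phenotype small enough for compact canvases used in fast tests
smallPhenotype <- function(...) {
  CellPhenotypeParams(cellRadiusMean = 8, cellRadiusSd = 1,
                      eccentricityMean = 0.2, eccentricitySd = 0.08, ...)
}

smallSpec <- function(nClasses = 2, nPerClass = 10, imageSize = 32,
                      separationDelta = 0, seed = 1) {
  syntheticSpec(nClasses, nPerClass, imageSize, separationDelta, seed,
                baseline = smallPhenotype())
}

# a datastore of lightweight random images; contents do not matter for
# split/vote/evaluation mechanics
fakeDatastore <- function(counts, side = 8, seed = 1) {
  labels <- rep(names(counts), counts)
  imgs <- withr::with_seed(seed, lapply(seq_along(labels), function(i)
    matrix(runif(side * side, 0, 255), side, side)))
  CellImageSet(imgs, labels,
               sourcePaths = sprintf("%s/img_%04d.png", labels,
                                     seq_along(labels)))
}

# write a small colour-image class tree to disk, returning its root
writeImageTree <- function(counts, side = 12, seed = 1) {
  root <- withr::local_tempdir(.local_envir = parent.frame())
  set.seed(seed)
  for (cls in names(counts)) {
    dir.create(file.path(root, cls))
    for (i in seq_len(counts[[cls]])) {
      a <- array(runif(side * side * 3), c(side, side, 3))
      EBImage::writeImage(EBImage::Image(aperm(a, c(2, 1, 3)),
                                         colormode = "Color"),
                          file.path(root, cls, sprintf("c%03d.png", i)))
    }
  }
  root
}

# fabricate a PredictionSet from predicted labels
makePredictionSet <- function(labels, classLevels, modelId = "m",
                              recordIds = NULL, scores = NULL) {
  n <- length(labels)
  k <- length(classLevels)
  if (is.null(scores)) {
    scores <- matrix(0.3 / max(k - 1, 1), n, k)
    scores[cbind(seq_len(n), match(labels, classLevels))] <- 0.7
    if (k == 1) scores[] <- 1
  }
  colnames(scores) <- classLevels
  new("PredictionSet",
      recordIds = recordIds %||% sprintf("r%05d", seq_len(n)),
      predictedLabels = labels, scores = scores, classNames = classLevels,
      modelId = modelId)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force majority-vote oracle: labelMat is records x models
bruteVote <- function(labelMat, meanScores, classLevels) {
  n <- nrow(labelMat)
  winners <- character(n)
  ties <- logical(n)
  for (i in seq_len(n)) {
    cnt <- sapply(classLevels, function(cl) sum(labelMat[i, ] == cl))
    mx <- max(cnt)
    cand <- classLevels[cnt == mx]
    ties[i] <- length(cand) > 1
    if (length(cand) > 1) {
      ms <- meanScores[i, cand]
      cand <- cand[ms == max(ms)]
      if (length(cand) > 1) cand <- sort(cand)[1]
    }
    winners[i] <- cand[1]
  }
  list(winners = winners, ties = ties)
}
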
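test_that("a single model's tally is its own predictions with count one", {
  ps <- makePredictionSet(c("A", "B", "A"), c("A", "B"))
  t1 <- tallyVotes(list(ps))
  expect_equal(t1@nModels, 1L)
  expect_equal(unname(rowSums(votes(t1))), rep(1, 3))
  expect_equal(votes(t1)[, "A"], c(1L, 0L, 1L), ignore_attr = TRUE)
  ens <- majorityVote(t1, list(ps))
  expect_identical(predictedLabels(ens), predictedLabels(ps))
  expect_false(any(tieBroken(ens)))
})

test_that("vote counts aggregate the 19-model roster correctly", {
  votesFor <- c(rep("A", 12), rep("B", 7))
  preds <- lapply(seq_along(votesFor), function(i)
    makePredictionSet(votesFor[i], c("A", "B", "C"), modelId = paste0("m", i)))
  tl <- tallyVotes(preds)
  expect_equal(tl@nModels, 19L)
  expect_equal(unname(votes(tl)[1, ]), c(12L, 7L, 0L))
})

test_that("plurality wins without an absolute majority; ties are broken by mean score", {
  # counts A:7, B:6, C:6 over 19 voters -> A wins outright
  votesFor <- c(rep("A", 7), rep("B", 6), rep("C", 6))
  preds <- lapply(seq_along(votesFor), function(i)
    makePredictionSet(votesFor[i], c("A", "B", "C"), modelId = paste0("m", i)))
  ens <- majorityVote(tallyVotes(preds), preds)
  expect_equal(predictedLabels(ens), "A")
  expect_equal(ens@winningCounts, 7L)
  expect_false(tieBroken(ens))

  # 1-1 tie broken by the higher mean score
  pA <- makePredictionSet("A", c("A", "B"),
                          scores = matrix(c(0.60, 0.40), 1), modelId = "m1")
  pB <- makePredictionSet("B", c("A", "B"),
                          scores = matrix(c(0.50, 0.50), 1), modelId = "m2")
  ens2 <- majorityVote(tallyVotes(list(pA, pB)), list(pA, pB))
  expect_equal(predictedLabels(ens2), "A")   # mean 0.55 vs 0.45
  expect_true(tieBroken(ens2))

  # equal mean scores fall back to lexicographic order
  pC <- makePredictionSet("B", c("A", "B"),
                          scores = matrix(c(0.40, 0.60), 1), modelId = "m3")
  ens3 <- majorityVote(tallyVotes(list(pA, pC)), list(pA, pC))
  expect_equal(predictedLabels(ens3), "A")
  expect_true(tieBroken(ens3))

  # unanimity
  all19 <- lapply(1:19, function(i)
    makePredictionSet("A", c("A", "B"), modelId = paste0("m", i)))
  ens4 <- majorityVote(tallyVotes(all19), all19)
  expect_equal(ens4@winningCounts, 19L)
  expect_false(tieBroken(ens4))
})

test_that("mismatched records or class universes are rejected with the difference", {
  p1 <- makePredictionSet(c("A", "B"), c("A", "B"),
                          recordIds = c("r1", "r2"))
  p2 <- makePredictionSet(c("A", "B"), c("A", "B"),
                          recordIds = c("r1", "r3"))
  expect_error(tallyVotes(list(p1, p2)), "r2|r3")
  p3 <- makePredictionSet(c("A", "B"), c("A", "B", "C"),
                          recordIds = c("r1", "r2"))
  expect_error(tallyVotes(list(p1, p3)), "C")
})

test_that("random vote tables match the brute-force oracle, including ties", {
  set.seed(99)
  for (rep in 1:50) {
    nModels <- sample(1:19, 1)
    k <- sample(2:10, 1)
    n <- sample(3:8, 1)
    classes <- LETTERS[seq_len(k)]
    labelMat <- matrix(sample(classes, n * nModels, replace = TRUE),
                       n, nModels)
    preds <- lapply(seq_len(nModels), function(m)
      makePredictionSet(labelMat[, m], classes, modelId = paste0("m", m)))
    tl <- tallyVotes(preds)
    expect_equal(unname(rowSums(votes(tl))), rep(nModels, n))
    ens <- majorityVote(tl, preds)
    meanScores <- Reduce(`+`, lapply(preds, scores)) / nModels
    colnames(meanScores) <- classes
    oracle <- bruteVote(labelMat, meanScores, classes)
    expect_identical(predictedLabels(ens), oracle$winners)
    expect_identical(tieBroken(ens), oracle$ties)
  }
})

test_that("model order never changes winners that were not tie-broken", {
  set.seed(5)
  classes <- c("A", "B", "C")
  preds <- lapply(1:7, function(m)
    makePredictionSet(sample(classes, 20, replace = TRUE), classes,
                      modelId = paste0("m", m)))
  e1 <- majorityVote(tallyVotes(preds), preds)
  perm <- sample(7)
  e2 <- majorityVote(tallyVotes(preds[perm]), preds[perm])
  keep <- !tieBroken(e1)
  expect_identical(predictedLabels(e1)[keep], predictedLabels(e2)[keep])
  expect_identical(tieBroken(e1), tieBroken(e2))
})

test_that("19 independent voters at p = 0.7 beat any single voter (Condorcet)", {
  set.seed(2024)
  n <- 10000
  truth <- sample(c("A", "B"), n, replace = TRUE)
  flip <- function() ifelse(runif(n) < 0.7, truth,
                            ifelse(truth == "A", "B", "A"))
  preds <- lapply(1:19, function(m)
    makePredictionSet(flip(), c("A", "B"), modelId = paste0("m", m)))
  ens <- majorityVote(tallyVotes(preds), preds)
  acc <- mean(predictedLabels(ens) == truth)
  expected <- sum(dbinom(10:19, 19, 0.7))   # majority-correct probability
  expect_gt(acc, 0.7)
  expect_lt(abs(acc - expected), 3 * sqrt(expected * (1 - expected) / n) + 0.002)
})
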
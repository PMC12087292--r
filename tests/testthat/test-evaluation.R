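test_that("confusion charts tabulate truth by prediction", {
  truth <- rep(c("A", "B", "C"), each = 10)
  perfect <- confusionChart(truth, truth)
  expect_equal(diag(chartCounts(perfect)), c(A = 10, B = 10, C = 10),
               ignore_attr = TRUE)
  expect_equal(sum(chartCounts(perfect)) - sum(diag(chartCounts(perfect))), 0)
  expect_equal(overallAccuracy(perfect), 100)

  ch <- confusionChart(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(unname(chartCounts(ch)["A", ]), c(1L, 1L))
  expect_equal(unname(chartCounts(ch)["B", ]), c(0L, 1L))
  expect_equal(unname(classSupport(ch)), c(2, 1))

  expect_error(confusionChart(character(0), character(0)), "empty")
  expect_error(confusionChart(c("A", "B"), "A"), "different lengths")
})

test_that("record identifiers must align between truth and predictions", {
  ds <- fakeDatastore(list(A = 2, B = 2))
  ps <- makePredictionSet(c("A", "A", "B", "B"), c("A", "B"),
                          recordIds = rev(sourcePaths(ds)))
  expect_error(confusionChart(ds, ps), "not aligned")
  ok <- makePredictionSet(c("A", "A", "B", "B"), c("A", "B"),
                          recordIds = sourcePaths(ds))
  expect_equal(overallAccuracy(confusionChart(ds, ok)), 100)
})

test_that("overall accuracy is trace over total and respects its bounds", {
  ch <- confusionChart(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(overallAccuracy(ch), 75)
  # uniform random predictions on balanced binary truth sit at chance
  set.seed(3)
  n <- 10000
  truth <- rep(c("A", "B"), each = n / 2)
  pred <- sample(c("A", "B"), n, replace = TRUE)
  acc <- overallAccuracy(confusionChart(truth, pred))
  expect_lt(abs(acc - 50), 3 * 100 * sqrt(0.25 / n))
})

test_that("chart conservation and the support-weighted accuracy identity hold", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    n <- sample(20:200, 1)
    classes <- LETTERS[seq_len(k)]
    truth <- sample(classes, n, replace = TRUE)
    truth[seq_len(k)] <- classes  # every class present
    pred <- ifelse(runif(n) < 0.6, truth, sample(classes, n, replace = TRUE))
    ch <- confusionChart(truth, pred)
    expect_equal(sum(chartCounts(ch)), n)
    expect_equal(unname(classSupport(ch)),
                 as.vector(table(factor(truth, classes))))
    pc <- perClassAccuracy(ch)
    expect_equal(overallAccuracy(ch),
                 sum(pc * classSupport(ch)) / sum(classSupport(ch)),
                 tolerance = 1e-12)
    expect_true(all(pc >= 0 & pc <= 100, na.rm = TRUE))
    expect_gte(balancedAccuracy(ch), 0)
  }
})

test_that("a one-backbone experiment's ensemble equals its single model", {
  spec <- smallSpec(nClasses = 2, nPerClass = 10, separationDelta = 1.5,
                    seed = 13)
  ds <- synthesizeDatastore(spec)
  rep1 <- runClassificationExperiment(ds, list(getBackbone("scnnC")),
                                      SplitSpec(seed = 2),
                                      TrainConfig(maxEpochs = 10, seed = 3))
  expect_equal(rep1@ensembleAccuracy, unname(rep1@modelAccuracies))
  expect_error(compareSingleVsEnsemble(rep1), "at least two")
})

test_that("binary and one-vs-rest experiments relabel and report correctly", {
  specA <- smallSpec(nClasses = 2, nPerClass = 10, separationDelta = 1.5,
                     seed = 23)
  ds <- synthesizeDatastore(specA)
  pos <- ds[imageLabels(ds) == "class_01"]
  neg <- ds[imageLabels(ds) == "class_02"]
  repB <- runBinaryExperiment(pos, neg, list(getBackbone("scnnC")),
                              SplitSpec(seed = 4),
                              TrainConfig(maxEpochs = 8, seed = 5),
                              labels = c("case", "control"))
  expect_equal(repB@chart@classNames, c("case", "control"))
  expect_equal(sum(chartCounts(repB@chart)), 4)  # 20% test fold of 20

  spec3 <- smallSpec(nClasses = 3, nPerClass = 10, separationDelta = 1,
                     seed = 33)
  ds3 <- synthesizeDatastore(spec3)
  repOVR <- runOneVsRestExperiment("class_01", ds3,
                                   list(getBackbone("scnnC")),
                                   SplitSpec(seed = 6),
                                   TrainConfig(maxEpochs = 8, seed = 7))
  expect_match(repOVR@notes, "1:2")
  expect_setequal(repOVR@chart@classNames, c("class_01", "rest"))
  # rest pools the other classes: support 2+2 in the test fold
  expect_equal(unname(classSupport(repOVR@chart)["rest"]), 4)
  expect_error(runOneVsRestExperiment("absent", ds3,
                                      list(getBackbone("scnnC"))),
               "absent")
})

test_that("the single-versus-ensemble comparison table does its arithmetic", {
  ch <- confusionChart(c("A", "B"), c("A", "B"))
  rep0 <- new("ExperimentReport", name = "toy",
              modelAccuracies = c(m1 = 80, m2 = 85, m3 = 82),
              ensembleAccuracy = 90,
              perClassAccuracy = c(A = 100, B = 100),
              balancedAccuracy = 100, chart = ch, config = list(),
              notes = character(0))
  cmp <- compareSingleVsEnsemble(rep0)
  expect_equal(cmp$summary$medianSingle, 82)
  expect_equal(cmp$summary$deltaVsMedian, 8)
  expect_equal(cmp$summary$minSingle, 80)
  expect_equal(cmp$summary$maxSingle, 85)
  rep0@ensembleAccuracy <- 82
  expect_equal(compareSingleVsEnsemble(rep0)$summary$deltaVsMedian, 0)
})

test_that("reports, predictions and charts persist faithfully", {
  spec <- smallSpec(nClasses = 2, nPerClass = 10, separationDelta = 1.5,
                    seed = 43)
  ds <- synthesizeDatastore(spec)
  rep1 <- runClassificationExperiment(ds, c("scnnC", "scnnE"),
                                      SplitSpec(seed = 2),
                                      TrainConfig(maxEpochs = 8, seed = 3))
  dir <- withr::local_tempdir()
  writeReport(rep1, file.path(dir, "report.json"))
  parsed <- jsonlite::read_json(file.path(dir, "report.json"),
                                simplifyVector = TRUE)
  expect_equal(parsed$ensembleAccuracy, rep1@ensembleAccuracy)
  expect_equal(parsed$config$hash, rep1@config$hash)

  writeConfusionCSV(rep1@chart, file.path(dir, "chart.csv"))
  grid <- read.csv(file.path(dir, "chart.csv"), check.names = FALSE)
  expect_equal(sum(grid[, -1]), sum(chartCounts(rep1@chart)))

  ens <- attr(rep1, "ensemblePrediction")
  ps <- predict(attr(rep1, "models")[[1]], ds[1:5])
  writePredictions(ps, file.path(dir, "pred.csv"))
  back <- readPredictions(file.path(dir, "pred.csv"))
  expect_identical(predictedLabels(back), predictedLabels(ps))
  expect_equal(scores(back), scores(ps), tolerance = 1e-12)
  # round-tripped predictions can be fused by the same engine
  tl <- tallyVotes(list(back, back))
  expect_equal(tl@nModels, 2L)
})
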
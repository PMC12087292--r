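test_that("stratified splitting follows the floor-and-remainder rule", {
  ds <- fakeDatastore(list(A = 100, B = 100))
  folds <- splitDataset(ds, SplitSpec(0.6, 0.2, 0.2, seed = 1))
  for (cls in c("A", "B")) {
    expect_equal(sum(imageLabels(folds$train) == cls), 60)
    expect_equal(sum(imageLabels(folds$validate) == cls), 20)
    expect_equal(sum(imageLabels(folds$test) == cls), 20)
  }

  ds7 <- fakeDatastore(list(A = 7, B = 7))
  f7 <- splitDataset(ds7, SplitSpec(0.6, 0.2, 0.2, seed = 2))
  expect_equal(sum(imageLabels(f7$validate) == "A"), 1)
  expect_equal(sum(imageLabels(f7$test) == "A"), 1)
  expect_equal(sum(imageLabels(f7$train) == "A"), 5)
  # disjoint and exhaustive
  all <- c(sourcePaths(f7$train), sourcePaths(f7$validate),
           sourcePaths(f7$test))
  expect_equal(sort(all), sort(sourcePaths(ds7)))
})

test_that("degenerate fractions and undersized classes behave per contract", {
  ds <- fakeDatastore(list(A = 5, B = 5))
  f <- splitDataset(ds, SplitSpec(1, 0, 0))
  expect_equal(length(f$train), 10)
  expect_equal(length(f$validate), 0)
  expect_equal(length(f$test), 0)
  expect_equal(classNames(f$validate), classNames(ds))

  tiny <- fakeDatastore(list(A = 2, B = 20))
  expect_error(splitDataset(tiny, SplitSpec(0.6, 0.2, 0.2)), "'A'")
})

test_that("splitting is deterministic given its seed", {
  ds <- fakeDatastore(list(A = 20, B = 20))
  a <- splitDataset(ds, SplitSpec(seed = 9))
  b <- splitDataset(ds, SplitSpec(seed = 9))
  expect_identical(sourcePaths(a$train), sourcePaths(b$train))
  d <- splitDataset(ds, SplitSpec(seed = 10))
  expect_false(identical(sourcePaths(a$train), sourcePaths(d$train)))
})

test_that("split conservation and stratification hold over random datasets", {
  set.seed(123)
  for (i in 1:30) {
    counts <- as.list(sample(5:30, sample(2:4, 1)))
    names(counts) <- paste0("c", seq_along(counts))
    ds <- fakeDatastore(counts, seed = i)
    folds <- splitDataset(ds, SplitSpec(seed = i))
    all <- c(sourcePaths(folds$train), sourcePaths(folds$validate),
             sourcePaths(folds$test))
    expect_equal(sort(all), sort(sourcePaths(ds)))
    expect_equal(anyDuplicated(all), 0L)
    for (cls in names(counts)) {
      n <- counts[[cls]]
      expect_lt(abs(sum(imageLabels(folds$validate) == cls) - 0.2 * n), 1)
      expect_lt(abs(sum(imageLabels(folds$test) == cls) - 0.2 * n), 1)
      expect_lt(abs(sum(imageLabels(folds$train) == cls) - 0.6 * n), 2)
    }
  }
})

test_that("a surrogate backbone memorises a small separable training set", {
  spec <- smallSpec(nClasses = 2, nPerClass = 10, separationDelta = 2,
                    seed = 21)
  ds <- synthesizeDatastore(spec)
  m <- fineTuneBackbone(ds, ds, getBackbone("scnnC"),
                        TrainConfig(maxEpochs = 40, seed = 4,
                                    earlyStoppingPatience = 40))
  expect_equal(max(trainingLog(m)$train_accuracy), 1)
  p <- predict(m, ds)
  expect_equal(predictedLabels(p), imageLabels(ds))
})

test_that("fine-tuning and prediction are deterministic given seeds", {
  spec <- smallSpec(nClasses = 2, nPerClass = 8, separationDelta = 1,
                    seed = 31)
  ds <- synthesizeDatastore(spec)
  folds <- splitDataset(ds, SplitSpec(0.5, 0.25, 0.25, seed = 1))
  cfg <- TrainConfig(maxEpochs = 20, seed = 8)
  m1 <- fineTuneBackbone(folds$train, folds$validate, getBackbone("scnnC"), cfg)
  m2 <- fineTuneBackbone(folds$train, folds$validate, getBackbone("scnnC"), cfg)
  p1 <- predict(m1, folds$test)
  p2 <- predict(m2, folds$test)
  expect_identical(scores(p1), scores(p2))
  expect_identical(predictedLabels(p1), predictedLabels(p2))
  expect_identical(trainingLog(m1), trainingLog(m2))
})

test_that("prediction sets preserve order, counts and score normalisation", {
  spec <- smallSpec(nClasses = 2, nPerClass = 6, separationDelta = 1,
                    seed = 41)
  ds <- synthesizeDatastore(spec)
  m <- fineTuneBackbone(ds, ds[integer(0)], getBackbone("scnnC"),
                        TrainConfig(maxEpochs = 5, seed = 1))
  probe <- ds[1:10]
  p <- predict(m, probe)
  expect_equal(length(p), 10)
  expect_identical(p@recordIds, sourcePaths(probe))
  expect_true(all(abs(rowSums(scores(p)) - 1) < 1e-6))
  expect_true(all(scores(p) >= 0))
  expect_identical(predictedLabels(p),
                   classNames(p)[max.col(scores(p), ties.method = "first")])
  # empty input -> empty prediction set
  p0 <- predict(m, ds[integer(0)])
  expect_equal(length(p0), 0)
})

test_that("label and registry misuse is rejected", {
  dsA <- fakeDatastore(list(A = 6))
  dsAB <- fakeDatastore(list(A = 3, B = 3))
  expect_error(fineTuneBackbone(dsA, dsAB, getBackbone("scnnC")),
               "absent from training")
  expect_error(fineTuneBackbone(dsAB, dsA, getBackbone("resnet18"),
                                TrainConfig(maxEpochs = 1)),
               "weight artifact")
  expect_error(getBackbone("nonesuch"), "unknown backbone")
  reg <- backboneRegistry()
  expect_equal(sum(reg$family == "published"), 17)
  expect_gte(sum(reg$family == "surrogate"), 3)
})

test_that("frozenDepth selects head-only versus dense-block fine-tuning", {
  spec <- smallSpec(nClasses = 2, nPerClass = 6, separationDelta = 1.5,
                    seed = 51)
  ds <- synthesizeDatastore(spec)
  bb <- getBackbone("scnnC")
  bbHead <- bb; bbHead@frozenDepth <- 1
  mHead5 <- fineTuneBackbone(ds, ds, bbHead, TrainConfig(maxEpochs = 5, seed = 2))
  mHead2 <- fineTuneBackbone(ds, ds, bbHead, TrainConfig(maxEpochs = 2, seed = 2))
  mBoth <- fineTuneBackbone(ds, ds, bb, TrainConfig(maxEpochs = 5, seed = 2))
  # head-only training leaves the dense block at its seeded initialisation
  expect_identical(mHead5@dense$W1, mHead2@dense$W1)
  expect_false(identical(mHead5@dense$W1, mBoth@dense$W1))
  bbZero <- bb; bbZero@frozenDepth <- 0
  expect_warning(fineTuneBackbone(ds, ds, bbZero,
                                  TrainConfig(maxEpochs = 2, seed = 2)),
                 "remains frozen")
})

test_that("a non-finite loss aborts with a diagnostic", {
  spec <- smallSpec(nClasses = 2, nPerClass = 6, separationDelta = 1, seed = 61)
  ds <- synthesizeDatastore(spec)
  expect_error(
    fineTuneBackbone(ds, ds, getBackbone("scnnC"),
                     TrainConfig(optimizer = "sgdm", learningRate = 1e308,
                                 maxEpochs = 5, seed = 1)),
    "non-finite")
})

test_that("models round-trip through disk with identical predictions", {
  spec <- smallSpec(nClasses = 2, nPerClass = 6, separationDelta = 1, seed = 71)
  ds <- synthesizeDatastore(spec)
  m <- fineTuneBackbone(ds, ds, getBackbone("scnnC"),
                        TrainConfig(maxEpochs = 5, seed = 3))
  stem <- file.path(withr::local_tempdir(), "model")
  saveModel(m, stem)
  m2 <- loadModel(stem)
  expect_identical(scores(predict(m, ds)), scores(predict(m2, ds)))
  expect_equal(classNames(m2), classNames(m))
  expect_true(file.exists(paste0(stem, ".json")))
  expect_true(file.exists(paste0(stem, "_log.csv")))
})
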
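test_that("fold assignment balances and separates subjects", {
  subj <- sprintf("P%03d", 1:140)
  f10 <- assignFolds(subj, 10, seed = 1)
  expect_identical(unname(tabulate(f10@mapping, 10)), rep(14L, 10))
  f3 <- assignFolds(subj, 3, seed = 1)
  expect_identical(sort(tabulate(f3@mapping, 3)), c(46L, 47L, 47L))
  for (k in 1:3) {
    fs <- foldSubjects(f3, k)
    expect_length(intersect(fs$train, fs$test), 0L)
    expect_setequal(c(fs$train, fs$test), subj)
  }
  expect_error(assignFolds(subj[1:5], 10), class = "painAU_invalid_input")
})

test_that("precision/recall/F1 agree with a counting oracle on 1000 random instances", {
  set.seed(17)
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    yt <- rbinom(n, 1, runif(1, 0.1, 0.9))
    yp <- rbinom(n, 1, runif(1, 0.1, 0.9))
    got <- f1PrecisionRecall(yt, yp)
    ## brute-force counting oracle
    tp <- 0; fp <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (yt[j] == 1 && yp[j] == 1) tp <- tp + 1
      if (yt[j] == 0 && yp[j] == 1) fp <- fp + 1
      if (yt[j] == 1 && yp[j] == 0) fn <- fn + 1
    }
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    expect_identical(unname(got), c(p, r, f))
  }
})

test_that("metric conventions handle perfect, empty and degenerate cases", {
  expect_equal(unname(f1PrecisionRecall(c(1, 0, 1), c(1, 0, 1))), c(1, 1, 1))
  expect_equal(unname(f1PrecisionRecall(c(1, 1, 0), c(0, 0, 0))), c(0, 0, 0))
  expect_true(all(is.na(
    f1PrecisionRecall(c(1, 1, 0), c(0, 0, 0), undefined = NA)[1])))
  expect_error(f1PrecisionRecall(c(1, 0), c(1, 0, 1)),
               class = "painAU_invalid_input")
})

test_that("rmse/mae follow their definitions", {
  expect_equal(unname(rmseMae(c(1, 2, 3), c(1, 2, 3))), c(0, 0))
  expect_equal(unname(rmseMae(c(0, 0), c(1, 3))), c(sqrt(5), 2))
  expect_error(rmseMae(numeric(0), numeric(0)),
               class = "painAU_invalid_input")
})

test_that("confusion-matrix metrics reproduce the published summed-matrix arithmetic", {
  cm <- confusionMatrix2x2(tn = 387, fp = 22, fn = 29, tp = 117)
  mm <- matrixMetrics(cm)
  expect_equal(unname(mm["accuracy"]), 504 / 555)
  expect_equal(roundHalfUp(100 * mm["accuracy"]), 90.81, ignore_attr = TRUE)
  expect_equal(unname(round(mm["precision"], 4)), 0.8417)
  expect_equal(unname(round(mm["recall"], 4)), 0.8014)
  expect_equal(unname(round(mm["f1"], 4)), 0.8211)
  expect_equal(unname(matrixMetrics(confusionMatrix2x2(5, 0, 0, 7))),
               c(1, 1, 1, 1))
  expect_equal(unname(matrixMetrics(confusionMatrix2x2(0, 0, 0, 10))),
               c(1, 1, 1, 1))
  expect_error(matrixMetrics(confusionMatrix2x2(0, 0, 0, 0)),
               class = "painAU_invalid_input")
})

test_that("reference row averages reproduce the published aggregate scores", {
  ref <- referenceBenchmark()
  mesh <- unlist(ref$auF1[ref$auF1$method == "landmark_fcn_mesh478", -1])
  expect_equal(roundHalfUp(mean(mesh)), 79.25, ignore_attr = TRUE)
  noaug <- unlist(ref$rareAuF1[ref$rareAuF1$method == "no_augmentation", -1])
  expect_equal(roundHalfUp(mean(noaug)), 16.31, ignore_attr = TRUE)
  aug <- unlist(ref$rareAuF1[
    ref$rareAuF1$method == "landmark_fcn_bp4d83_augmented", -1])
  expect_equal(roundHalfUp(mean(aug)), 31.16, ignore_attr = TRUE)
  ie <- ref$intensityError
  expect_equal(roundHalfUp(mean(unlist(
    ie[ie$method == "landmark_fcn" & ie$metric == "rmse", -(1:2)]))), 0.66,
    ignore_attr = TRUE)
  expect_equal(roundHalfUp(mean(unlist(
    ie[ie$method == "landmark_fcn" & ie$metric == "mae", -(1:2)]))), 0.44,
    ignore_attr = TRUE)
})

test_that("emitted reports are self-consistent (AVG equals the mean of its cells)", {
  perAU <- data.frame(au = c(paste0("AU", auDetectIds()), "AVG"),
                      f1 = c(1:8, mean(1:8)))
  rep <- painAU:::.makeAUReport("au_detection", perAU, data.frame())
  expect_s4_class(rep, "EvalReport")
  bad <- perAU
  bad$f1[9] <- 7.77
  expect_error(painAU:::.makeAUReport("au_detection", bad, data.frame()),
               "AVG")
})

test_that("cross-validated AU detection on the small simulation produces a consistent report", {
  ds <- smallDataset()
  cfg <- auDetectorConfig(inputSize = 249L, maxEpochs = 20L, seed = 2L)
  rep <- runAUCV(ds, tpl83, k = 2L, config = cfg, frameStride = 4L, seed = 3L)
  df <- rep@perAU
  cells <- df$f1[df$au != "AVG"]
  expect_equal(df$f1[df$au == "AVG"], mean(cells), tolerance = 5e-3)
  expect_true(all(cells >= 0 & cells <= 100))
  expect_identical(nrow(rep@folds), 2L)
})

test_that("cross-validated intensity estimation reports self-consistent RMSE/MAE", {
  ds <- smallDataset()
  cfg <- auDetectorConfig(inputSize = 249L, outputUnits = 5L,
                          learningRate = 0.005, maxEpochs = 15L, seed = 6L)
  rep <- runIntensityCV(ds, tpl83, k = 2L, config = cfg, frameStride = 6L,
                        seed = 7L)
  df <- rep@perAU
  expect_equal(df$rmse[df$au == "AVG"], mean(df$rmse[df$au != "AVG"]),
               tolerance = 5e-3)
  expect_true(all(df$rmse >= 0) && all(df$mae <= df$rmse + 1e-9))
})

test_that("cross-validated pain detection sums fold confusions consistently", {
  ds <- smallDataset()
  cfg <- painLSTMConfig(naInput = 8L, hiddenDim = 16L, learningRate = 3e-3,
                        maxEpochs = 8L, seed = 4L)
  rep <- runPainCV(ds, cfg, k = 2L, auSource = "ground8",
                   windowLength = 100L, seed = 5L)
  expect_equal(sum(rep@confusion), 32)   # every segment judged once
  mm <- matrixMetrics(rep@confusion)
  expect_equal(rep@summary$accuracy, roundHalfUp(100 * mm["accuracy"]),
               ignore_attr = TRUE)
  expect_error(runPainCV(ds, cfg, k = 2L, auSource = "predicted8"),
               class = "painAU_missing_artifact")
})
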
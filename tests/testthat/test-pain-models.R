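## A minimal hand-built dataset of ground-truth AU segments for
## windowing tests (no rendering needed: windowing reads labels only).
labelOnlySegment <- function(tn, segClass, id, subj = "W1") {
  pres <- matrix(rbinom(tn * 8, 1, 0.2), tn, 8)
  LandmarkSequence(array(rnorm(tn * 5 * 3), c(tn, 5, 3)),
                   subjectId = subj, segmentId = id,
                   segmentClass = segClass, auPresence = pres)
}

test_that("windowing follows the stride and right-alignment policy", {
  ds <- LandmarkDataset(list(labelOnlySegment(500, "pain", "a")))
  w <- windowSegments(ds, windowLength = 350L)
  expect_length(w, 2L)
  expect_true(all(w[[1]]$valid))
  expect_true(all(w[[2]]$valid))
  ## windows cover frames 1-350 and 151-500
  expect_equal(w[[2]]$A,
               auPresence(segments(ds)[[1]])[151:500, ],
               ignore_attr = TRUE)
  expect_identical(w[[1]]$y, 1L)

  exact <- windowSegments(LandmarkDataset(list(
    labelOnlySegment(350, "other", "b"))), 350L)
  expect_length(exact, 1L)
  expect_true(all(exact[[1]]$valid))
  expect_identical(exact[[1]]$y, 0L)

  short <- windowSegments(LandmarkDataset(list(
    labelOnlySegment(200, "other", "c"))), 350L)
  expect_length(short, 1L)
  expect_identical(sum(short[[1]]$valid), 200L)
  expect_true(all(short[[1]]$A[201:350, ] == 0))

  expect_warning(
    tiny <- windowSegments(LandmarkDataset(list(
      labelOnlySegment(5, "other", "d"))), 350L),
    "skipped")
  expect_length(tiny, 0L)
})

test_that("the prediction label is round(probability)", {
  expect_identical(as.integer(round(0.49)), 0L)
  w <- list(A = matrix(0, 4, 3), valid = rep(TRUE, 4), y = 0)
  cfg <- painTransformerConfig(naInput = 3L, projectionDim = 8L,
                               numHeads = 2L, numLayers = 1L, ffDim = 8L,
                               mlpHidden = 4L, dropout = 0, seed = 1L)
  m <- new("PainTransformer", params = painAU:::.tfInit(cfg),
           config = unclass(cfg), history = data.frame())
  p <- predictPain(m, w)
  expect_true(p >= 0 && p <= 1)
})

test_that("training rejects single-class window sets and mismatched dimensions", {
  ws <- lapply(1:4, function(i)
    list(A = matrix(rnorm(24), 8), valid = rep(TRUE, 8), y = 1L,
         subjectId = "s", segmentId = paste0("g", i)))
  cfg <- painLSTMConfig(naInput = 3L, hiddenDim = 4L, maxEpochs = 1L)
  expect_error(trainPainModel(ws, cfg), class = "painAU_contract_violation")
  ws[[1]]$y <- 0L
  bad <- painLSTMConfig(naInput = 5L, hiddenDim = 4L, maxEpochs = 1L)
  expect_error(trainPainModel(ws, bad), class = "painAU_invalid_input")
})

test_that("configs echo the reference architecture settings", {
  cfg <- painTransformerConfig()
  expect_identical(cfg$projectionDim, 1024L)
  expect_identical(cfg$numHeads, 4L)
  expect_identical(cfg$numLayers, 2L)
  expect_equal(cfg$learningRate, 1e-5)
  expect_identical(cfg$batchSize, 16L)
  expect_identical(cfg$maxEpochs, 150L)
  lcfg <- painLSTMConfig()
  expect_identical(lcfg$hiddenDim, 512L)
  expect_identical(lcfg$numLayers, 2L)
  expect_equal(lcfg$learningRate, 1e-3)
  expect_error(painTransformerConfig(projectionDim = 10L, numHeads = 4L),
               class = "painAU_invalid_input")
})

test_that("both models learn a sustained-activation rule and beat the majority baseline", {
  ## pain windows: sustained activation of the pain-overlap AUs (6, 9, 18);
  ## other windows: sporadic activation elsewhere
  set.seed(33)
  mkWindow <- function(y, subj, id) {
    A <- matrix(rbinom(60 * 8, 1, 0.08), 60, 8)
    if (y == 1) A[15:45, c(2, 4, 8)] <- 1   # AU6, AU9, AU18 columns
    list(A = A, valid = rep(TRUE, 60), y = as.integer(y), subjectId = subj,
         segmentId = id)
  }
  train <- c(lapply(1:10, function(i) mkWindow(1, paste0("tr", i), paste0("p", i))),
             lapply(1:20, function(i) mkWindow(0, paste0("tr", i), paste0("n", i))))
  test <- c(lapply(1:6, function(i) mkWindow(1, paste0("te", i), paste0("tp", i))),
            lapply(1:12, function(i) mkWindow(0, paste0("te", i), paste0("tn", i))))
  truth <- vapply(test, `[[`, numeric(1), "y")
  majority <- max(mean(truth == 0), mean(truth == 1))

  tcfg <- painTransformerConfig(naInput = 8L, projectionDim = 32L,
                                numHeads = 4L, numLayers = 1L, ffDim = 64L,
                                mlpHidden = 16L, learningRate = 2e-3,
                                maxEpochs = 30L, seed = 3L)
  mt <- trainPainModel(train, tcfg)
  accT <- mean((predictPain(mt, test) >= 0.5) == truth)

  lcfg <- painLSTMConfig(naInput = 8L, hiddenDim = 24L, learningRate = 3e-3,
                         maxEpochs = 20L, seed = 3L)
  ml <- trainPainModel(train, lcfg)
  accL <- mean((predictPain(ml, test) >= 0.5) == truth)

  expect_gte(accT, 0.95)
  expect_gte(accL, 0.95)
  expect_gt(accT, majority)
  expect_gt(accL, majority)
})

test_that("windows can carry all ground-truth AUs or per-frame detector scores", {
  ds <- smallDataset()
  wAll <- windowSegments(ds, windowLength = 100L, auSource = "groundAll")
  expect_identical(ncol(wAll[[1]]$A), length(auUniverse()))
  expect_true(all(vapply(wAll, function(w) all(w$A %in% c(0, 1)), logical(1))))
  expect_error(windowSegments(ds, 100L, auSource = "predicted8"),
               class = "painAU_missing_artifact")
})

test_that("segment aggregation takes the majority vote with ties deciding pain", {
  ws <- list(
    list(A = matrix(0, 2, 1), valid = c(TRUE, TRUE), y = 1L,
         subjectId = "s1", segmentId = "segA"),
    list(A = matrix(0, 2, 1), valid = c(TRUE, TRUE), y = 1L,
         subjectId = "s1", segmentId = "segA"),
    list(A = matrix(0, 2, 1), valid = c(TRUE, TRUE), y = 0L,
         subjectId = "s2", segmentId = "segB"))
  agg <- aggregateSegments(ws, c(0.9, 0.1, 0.2))   # segA split 1-1 -> pain
  expect_identical(agg$label[agg$segmentId == "segA"], 1L)
  expect_identical(agg$label[agg$segmentId == "segB"], 0L)
})
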
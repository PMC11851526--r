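## Noise-free separable fixture: each AU drives its own displacement
## field, so frame geometry determines the labels exactly.
separableFrames <- function(n, seed) {
  set.seed(seed)
  ids <- as.character(auDetectIds())
  Y <- matrix(rbinom(n * 8, 1, 0.3), n, 8)
  X <- matrix(NA_real_, n, 3 * nrow(tpl83))
  for (i in seq_len(n)) {
    fr <- tpl83
    for (j in 1:8) if (Y[i, j] == 1)
      fr <- fr + (2.5 / 5) * basis83@fields[[ids[j]]]
    X[i, ] <- flattenFrame(fr)
  }
  list(X = X, Y = Y)
}

test_that("analytic gradients match central finite differences", {
  set.seed(1)
  X <- matrix(rnorm(10 * 9), 10)
  for (mode in c("logistic", "linear")) {
    Y <- if (mode == "logistic") matrix(rbinom(30, 1, 0.5), 10)
         else matrix(runif(30, 0, 5), 10)
    params <- painAU:::.denseInit(9, 6, 3, 2)
    an <- painAU:::.denseLossGrad(params, X, Y, mode)$grads
    v0 <- flatParams(params)
    eps <- 1e-6
    num <- vapply(seq_along(v0), function(i) {
      vp <- v0; vp[i] <- vp[i] + eps
      vm <- v0; vm[i] <- vm[i] - eps
      (painAU:::.denseLossGrad(unflatParams(vp, params), X, Y, mode)$loss -
       painAU:::.denseLossGrad(unflatParams(vm, params), X, Y, mode)$loss) /
        (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(num - flatParams(an))), 1e-5)
  }
})

test_that("the detector separates a noise-free one-field-per-AU fixture perfectly", {
  tr <- separableFrames(300, 21)
  te <- separableFrames(120, 22)
  cfg <- auDetectorConfig(inputSize = ncol(tr$X), maxEpochs = 50L, seed = 1L)
  model <- trainAUDetector(tr$X, tr$Y, cfg)
  expect_identical(model@config$inputSize, 249L)    # 3 x 83
  scores <- predictAU(model, te$X)
  expect_true(all(scores >= 0 & scores <= 1))
  pred <- binarizeAU(scores)
  f1 <- vapply(1:8, function(j)
    f1PrecisionRecall(te$Y[, j], pred[, j])["f1"], numeric(1))
  expect_true(all(f1 == 1))
})

test_that("training is reproducible under a fixed seed", {
  tr <- separableFrames(80, 31)
  cfg <- auDetectorConfig(inputSize = ncol(tr$X), maxEpochs = 5L, seed = 7L)
  m1 <- trainAUDetector(tr$X, tr$Y, cfg)
  m2 <- trainAUDetector(tr$X, tr$Y, cfg)
  expect_identical(m1@history$loss, m2@history$loss)
  expect_identical(m1@params, m2@params)
})

test_that("an AU without positives trains with a warning", {
  tr <- separableFrames(60, 41)
  tr$Y[, 3] <- 0
  expect_warning(
    trainAUDetector(tr$X, tr$Y,
                    auDetectorConfig(inputSize = ncol(tr$X), maxEpochs = 2L)),
    "AU")
})

test_that("binarization applies the threshold definition and boundaries", {
  s <- c(0.6, 0.4, 0.5, 0.99, 0, 1, 0.3, 0.7)
  expect_equal(binarizeAU(s), c(1, 0, 1, 1, 0, 1, 0, 1))
  expect_equal(binarizeAU(s, threshold = 0), rep(1, 8))
  expect_equal(binarizeAU(s, threshold = 1.01), rep(0, 8))
})

test_that("the intensity estimator recovers a linear intensity-displacement fixture", {
  set.seed(5)
  ids <- as.character(auIntensityIds())
  gen <- function(n) {
    Y <- matrix(runif(n * 5, 0, 5), n, 5)
    X <- matrix(NA_real_, n, 3 * nrow(tpl83))
    for (i in seq_len(n)) {
      fr <- tpl83
      for (j in 1:5) fr <- fr + (Y[i, j] / 5) * basis83@fields[[ids[j]]]
      X[i, ] <- flattenFrame(fr)
    }
    list(X = X, Y = Y)
  }
  tr <- gen(400); te <- gen(150)
  cfg <- auDetectorConfig(inputSize = ncol(tr$X), outputUnits = 5L,
                          learningRate = 0.005, maxEpochs = 150L, seed = 2L)
  model <- trainIntensityEstimator(tr$X, tr$Y, cfg)
  pred <- predictIntensity(model, te$X)
  expect_true(all(pred >= 0 & pred <= 5))
  rmse <- mean(vapply(1:5, function(j)
    rmseMae(te$Y[, j], pred[, j])["rmse"], numeric(1)))
  expect_lte(rmse, 0.05)
})

test_that("intensity training requires labels and predictions clamp to [0, 5]", {
  expect_error(trainIntensityEstimator(matrix(1, 2, 3), NULL),
               class = "painAU_contract_violation")
  m <- new("AUNet",
           params = list(W1 = matrix(0, 3, 2), b1 = c(0, 0),
                         W2 = matrix(0, 2, 5), b2 = c(5.7, -0.3, 2, 0, 5)),
           outputType = "linear", auIds = auIntensityIds(),
           config = list(), history = data.frame())
  out <- predictIntensity(m, c(1, 1, 1))
  expect_equal(unname(out[1, ]), c(5, 0, 2, 0, 5))
})

test_that("intensity rounding is nearest-integer, half away from zero, clamped", {
  expect_equal(roundIntensity(c(2.4, 2.5, -0.2, 5.9, 0.49, 4.5)),
               c(2, 3, 0, 5, 0, 5))
  expect_equal(roundIntensity(0:5), 0:5)
})

test_that("prediction rejects mismatched input sizes", {
  tr <- separableFrames(60, 51)
  m <- trainAUDetector(tr$X, tr$Y,
                       auDetectorConfig(inputSize = ncol(tr$X), maxEpochs = 2L))
  expect_error(predictAU(m, numeric(10)), class = "painAU_invalid_input")
})

test_that("training-order permutation under different seeds leaves metrics stable", {
  tr <- separableFrames(200, 61)
  te <- separableFrames(100, 62)
  f1s <- vapply(1:3, function(s) {
    m <- trainAUDetector(tr$X, tr$Y,
      auDetectorConfig(inputSize = ncol(tr$X), maxEpochs = 30L, seed = s))
    pred <- binarizeAU(predictAU(m, te$X))
    mean(vapply(1:8, function(j)
      f1PrecisionRecall(te$Y[, j], pred[, j])["f1"], numeric(1)))
  }, numeric(1))
  expect_lt(max(f1s) - min(f1s), 0.02)
})
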
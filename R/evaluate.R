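#' Subject-independent fold assignment
#'
#' Randomly partitions subjects into `k` folds whose sizes differ by at
#' most one; every evaluation in this package trains and tests on
#' disjoint subject sets (no person contributes frames to both sides).
#'
#' @param subjectIds Character vector of unique subject ids.
#' @param k Fold count.
#' @param seed Integer seed.
#' @return A [FoldAssignment-class].
#' @export
assignFolds <- function(subjectIds, k, seed = 1L) {
  subjectIds <- unique(as.character(subjectIds))
  if (k > length(subjectIds))
    .stopf("painAU_invalid_input",
           "k = %d folds but only %d subjects", k, length(subjectIds))
  ord <- .withSeed(seed, sample(subjectIds))
  mapping <- stats::setNames(rep(seq_len(k), length.out = length(ord)), ord)
  new("FoldAssignment", k = as.integer(k), mapping = mapping,
      seed = as.integer(seed))
}

#' @rdname assignFolds
#' @param folds A `FoldAssignment`.
#' @param fold Fold index.
#' @return `foldSubjects()`: list with `train` and `test` subject ids.
#' @export
foldSubjects <- function(folds, fold) {
  list(train = names(folds@mapping)[folds@mapping != fold],
       test = names(folds@mapping)[folds@mapping == fold])
}

#' Precision, recall and F1
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `F1 = 2PR / (P + R)`. Empty denominators yield 0 by default (the
#' usual convention for rare classes), or NA with `undefined = NA`.
#'
#' @param yTrue,yPred Equal-length binary vectors.
#' @param positive The positive label (default 1).
#' @param undefined Value for empty denominators (0 or NA).
#' @return Named numeric: `precision`, `recall`, `f1`.
#' @export
f1PrecisionRecall <- function(yTrue, yPred, positive = 1, undefined = 0) {
  if (length(yTrue) != length(yPred))
    .stopf("painAU_invalid_input", "length mismatch: %d vs %d",
           length(yTrue), length(yPred))
  tp <- sum(yTrue == positive & yPred == positive)
  fp <- sum(yTrue != positive & yPred == positive)
  fn <- sum(yTrue == positive & yPred != positive)
  p <- if (tp + fp == 0) undefined else tp / (tp + fp)
  r <- if (tp + fn == 0) undefined else tp / (tp + fn)
  f <- if (isTRUE(p + r == 0) || is.na(p + r)) undefined else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f)
}

#' RMSE and MAE
#'
#' @param yTrue,yPred Equal-length numeric vectors.
#' @return Named numeric: `rmse`, `mae`.
#' @export
rmseMae <- function(yTrue, yPred) {
  if (!length(yTrue) || length(yTrue) != length(yPred))
    .stopf("painAU_invalid_input", "inputs must be equal-length and non-empty")
  c(rmse = sqrt(mean((yTrue - yPred)^2)), mae = mean(abs(yTrue - yPred)))
}

#' 2x2 confusion matrix and its derived metrics
#'
#' The class convention is positive = pain; rows are truth
#' (other, pain), columns predictions.
#'
#' @param tn,fp,fn,tp Nonnegative counts.
#' @return `confusionMatrix2x2()`: a labeled 2x2 matrix.
#' @examples
#' cm <- confusionMatrix2x2(tn = 387, fp = 22, fn = 29, tp = 117)
#' matrixMetrics(cm)  # accuracy 504/555
#' @export
confusionMatrix2x2 <- function(tn, fp, fn, tp) {
  stopifnot(tn >= 0, fp >= 0, fn >= 0, tp >= 0)
  matrix(c(tn, fn, fp, tp), 2, 2,
         dimnames = list(truth = c("other", "pain"),
                         predicted = c("other", "pain")))
}

#' @rdname confusionMatrix2x2
#' @param cm A 2x2 confusion matrix from `confusionMatrix2x2()`.
#' @return `matrixMetrics()`: named numeric `accuracy`, `precision`,
#'   `recall`, `f1` (proportions in `[0, 1]`).
#' @export
matrixMetrics <- function(cm) {
  stopifnot(identical(dim(cm), c(2L, 2L)))
  total <- sum(cm)
  if (total == 0)
    .stopf("painAU_invalid_input", "confusion matrix has zero total")
  tn <- cm["other", "other"]; fp <- cm["other", "pain"]
  fn <- cm["pain", "other"]; tp <- cm["pain", "pain"]
  yT <- rep(c(0, 1, 1, 0), c(tn, fn, tp, fp))
  yP <- rep(c(0, 0, 1, 1), c(tn, fn, tp, fp))
  c(accuracy = (tp + tn) / total, f1PrecisionRecall(yT, yP))
}

## ------------------------------------------------------------------
## EvalReport

#' EvalReport: evaluation tables with self-consistent aggregates
#'
#' Holds per-AU (or per-fold) metric tables plus aggregates; on
#' construction the AVG column is checked to equal the mean of its row's
#' per-AU cells (within 5e-3 on the percent scale).
#'
#' @slot task `"au_detection"`, `"intensity"` or `"pain"`.
#' @slot perAU Per-AU metric data frame (with an `AVG` attribute-style
#'   final row where applicable).
#' @slot folds Per-fold metric data frame.
#' @slot confusion Summed 2x2 confusion matrix (pain task).
#' @slot summary Named list of aggregate values.
#' @export
setClass("EvalReport",
  representation(task = "character", perAU = "data.frame",
                 folds = "data.frame", confusion = "matrix",
                 summary = "list"))

setValidity("EvalReport", function(object) {
  df <- object@perAU
  if (nrow(df) && "AVG" %in% df$au) {
    cells <- df[df$au != "AVG", -1, drop = FALSE]
    avg <- df[df$au == "AVG", -1, drop = FALSE]
    for (j in seq_along(avg))
      if (abs(avg[[j]] - mean(cells[[j]])) > 5e-3)
        return(sprintf("AVG of column '%s' is not the mean of its cells",
                       names(avg)[j]))
  }
  TRUE
})

setMethod("show", "EvalReport", function(object) {
  cat(renderReport(object))
})

.makeAUReport <- function(task, perAU, folds, confusion = matrix(NA_real_, 0, 0),
                          summary = list()) {
  new("EvalReport", task = task, perAU = perAU, folds = folds,
      confusion = confusion, summary = summary)
}

#' Render an EvalReport as an aligned text table
#'
#' @param report An [EvalReport-class].
#' @return Character scalar (multi-line table).
#' @export
renderReport <- function(report) {
  out <- sprintf("== EvalReport: %s ==\n", report@task)
  if (nrow(report@perAU)) {
    df <- report@perAU
    df[-1] <- lapply(df[-1], function(x) sprintf("%.2f", x))
    out <- c(out, paste(utils::capture.output(print(df, row.names = FALSE)),
                        collapse = "\n"), "\n")
  }
  if (nrow(report@folds)) {
    df <- report@folds
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.2f", x))
    out <- c(out, paste(utils::capture.output(print(df, row.names = FALSE)),
                        collapse = "\n"), "\n")
  }
  if (nrow(report@confusion)) {
    out <- c(out, "Summed confusion matrix (rows = truth):\n",
             paste(utils::capture.output(print(report@confusion)),
                   collapse = "\n"), "\n")
  }
  if (length(report@summary))
    out <- c(out, paste(sprintf("%s: %.4g", names(report@summary),
                                unlist(report@summary)), collapse = "\n"),
             "\n")
  paste(out, collapse = "")
}

#' Write an EvalReport to CSV + JSON
#'
#' @param report An [EvalReport-class].
#' @param prefix Output path prefix; writes `<prefix>_perAU.csv`,
#'   `<prefix>_folds.csv` and `<prefix>.json`.
#' @export
writeReport <- function(report, prefix) {
  if (nrow(report@perAU))
    utils::write.csv(report@perAU, paste0(prefix, "_perAU.csv"),
                     row.names = FALSE)
  if (nrow(report@folds))
    utils::write.csv(report@folds, paste0(prefix, "_folds.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(task = report@task, summary = report@summary,
         confusion = if (nrow(report@confusion)) report@confusion else NULL),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

## ------------------------------------------------------------------
## Cross-validated protocols

#' Subject-independent cross-validated AU detection
#'
#' For each of `k` folds: trains the AU detector on the training
#' subjects' frames (optionally after rare-AU oversampling of the
#' training split only), predicts the held-out subjects' frames, and
#' scores per-AU F1. Reported per-AU values are averaged over folds and
#' the AVG column is their unweighted mean.
#'
#' @param dataset A labeled [LandmarkDataset-class].
#' @param template Normalization template.
#' @param k Fold count (3 in the reference protocol).
#' @param config An [auDetectorConfig()].
#' @param frameStride Frame subsampling stride for desk-scale runs.
#' @param augSpec Optional [augmentationSpec()] enabling oversampling.
#' @param augTargets AU ids to oversample (default [auDetectIds()]).
#' @param copies Copies per positive frame when augmenting.
#' @param mirror Optional [MirrorMap-class] for flip augmentation.
#' @param seed Fold-assignment seed.
#' @return An [EvalReport-class] (F1 values on the percent scale).
#' @export
runAUCV <- function(dataset, template, k = 3L,
                    config = auDetectorConfig(), frameStride = 1L,
                    augSpec = NULL, augTargets = auDetectIds(),
                    copies = 4L, mirror = NULL, seed = 1L) {
  folds <- assignFolds(manifest(dataset)$subjectId, k, seed)
  auNames <- paste0("AU", auDetectIds())
  perFold <- matrix(NA_real_, k, length(auNames),
                    dimnames = list(NULL, auNames))
  for (f in seq_len(k)) {
    fs <- foldSubjects(folds, f)
    stopifnot(length(intersect(fs$train, fs$test)) == 0L)
    trainDs <- subsetBySubject(dataset, fs$train, split = "train")
    if (!is.null(augSpec))
      trainDs <- oversampleRare(trainDs, augTargets, copies, augSpec, mirror)
    tr <- frameMatrix(trainDs, template, frameStride, "presence")
    te <- frameMatrix(subsetBySubject(dataset, fs$test, split = "test"),
                      template, frameStride, "presence")
    cfg <- config
    cfg$seed <- deriveSeed(config$seed, paste0("fold", f))
    model <- trainAUDetector(tr$X, tr$Y, cfg)
    pred <- binarizeAU(predictAU(model, te$X), config$threshold)
    for (j in seq_along(auNames))
      perFold[f, j] <- f1PrecisionRecall(te$Y[, j], pred[, j])["f1"]
  }
  perAU <- data.frame(au = c(auNames, "AVG"),
                      f1 = .pct(c(colMeans(perFold), mean(colMeans(perFold)))))
  foldsDf <- data.frame(fold = seq_len(k), macroF1 = .pct(rowMeans(perFold)))
  .makeAUReport("au_detection", perAU, foldsDf,
                summary = list(macroF1 = .pct(mean(perFold))))
}

#' Subject-independent cross-validated intensity estimation
#'
#' As [runAUCV()], for the 5-AU intensity regressor, reporting RMSE and
#' MAE per AU (fold-averaged) with unweighted AVG.
#'
#' @inheritParams runAUCV
#' @return An [EvalReport-class] (intensity units).
#' @export
runIntensityCV <- function(dataset, template, k = 3L,
                           config = auDetectorConfig(outputUnits = 5L),
                           frameStride = 1L, seed = 1L) {
  folds <- assignFolds(manifest(dataset)$subjectId, k, seed)
  auNames <- paste0("AU", auIntensityIds())
  rmseF <- maeF <- matrix(NA_real_, k, length(auNames),
                          dimnames = list(NULL, auNames))
  for (f in seq_len(k)) {
    fs <- foldSubjects(folds, f)
    tr <- frameMatrix(subsetBySubject(dataset, fs$train), template,
                      frameStride, "intensity")
    te <- frameMatrix(subsetBySubject(dataset, fs$test), template,
                      frameStride, "intensity")
    cfg <- config
    cfg$seed <- deriveSeed(config$seed, paste0("fold", f))
    model <- trainIntensityEstimator(tr$X, tr$Y, cfg)
    pred <- predictIntensity(model, te$X)
    for (j in seq_along(auNames)) {
      m <- rmseMae(te$Y[, j], pred[, j])
      rmseF[f, j] <- m["rmse"]; maeF[f, j] <- m["mae"]
    }
  }
  perAU <- data.frame(
    au = c(auNames, "AVG"),
    rmse = c(colMeans(rmseF), mean(colMeans(rmseF))),
    mae = c(colMeans(maeF), mean(colMeans(maeF))))
  .makeAUReport("intensity", perAU,
                data.frame(fold = seq_len(k), rmse = rowMeans(rmseF),
                           mae = rowMeans(maeF)),
                summary = list(rmse = mean(rmseF), mae = mean(maeF)))
}

#' Subject-independent cross-validated pain detection
#'
#' For each of `k` folds (10 in the reference protocol): trains the
#' chosen temporal classifier on the training subjects' AU windows and
#' evaluates held-out subjects at the segment level (majority vote over
#' a segment's windows, ties deciding pain). In `predicted8` mode an AU
#' detector is first trained on the same training subjects, so the
#' detector never sees test subjects either. Reports per-fold accuracy
#' and F1 plus the confusion matrix summed over folds (with its derived
#' aggregate metrics).
#'
#' @param dataset A labeled [LandmarkDataset-class].
#' @param modelConfig A [painTransformerConfig()] or [painLSTMConfig()].
#' @param k Fold count.
#' @param auSource `"ground8"`, `"groundAll"` or `"predicted8"`.
#' @param windowLength,stride,tailFrac Windowing policy (see
#'   [windowSegments()]).
#' @param detectorConfig An [auDetectorConfig()] (predicted8 only).
#' @param template Normalization template (predicted8 only).
#' @param frameStride Detector-training frame stride (predicted8 only).
#' @param seed Fold-assignment seed.
#' @return An [EvalReport-class].
#' @export
runPainCV <- function(dataset, modelConfig, k = 10L,
                      auSource = c("ground8", "groundAll", "predicted8"),
                      windowLength = 350L, stride = windowLength,
                      tailFrac = 0.4, detectorConfig = NULL,
                      template = NULL, frameStride = 1L, seed = 1L) {
  auSource <- match.arg(auSource)
  if (auSource == "predicted8" && (is.null(detectorConfig) || is.null(template)))
    .stopf("painAU_missing_artifact",
           "auSource 'predicted8' needs detectorConfig and template to train the per-fold AU detector")
  folds <- assignFolds(manifest(dataset)$subjectId, k, seed)
  cmSum <- confusionMatrix2x2(0, 0, 0, 0)
  foldRows <- list()
  for (f in seq_len(k)) {
    fs <- foldSubjects(folds, f)
    stopifnot(length(intersect(fs$train, fs$test)) == 0L)
    trainDs <- subsetBySubject(dataset, fs$train, split = "train")
    testDs <- subsetBySubject(dataset, fs$test, split = "test")
    detector <- NULL
    if (auSource == "predicted8") {
      tr <- frameMatrix(trainDs, template, frameStride, "presence")
      dcfg <- detectorConfig
      dcfg$seed <- deriveSeed(detectorConfig$seed, paste0("det-fold", f))
      detector <- trainAUDetector(tr$X, tr$Y, dcfg)
    }
    wTrain <- windowSegments(trainDs, windowLength, stride, tailFrac,
                             auSource, detector, template)
    wTest <- windowSegments(testDs, windowLength, stride, tailFrac,
                            auSource, detector, template)
    cfg <- modelConfig
    cfg$seed <- deriveSeed(modelConfig$seed, paste0("fold", f))
    model <- trainPainModel(wTrain, cfg)
    segs <- aggregateSegments(wTest, predictPain(model, wTest))
    cm <- confusionMatrix2x2(
      tn = sum(segs$truth == 0 & segs$label == 0),
      fp = sum(segs$truth == 0 & segs$label == 1),
      fn = sum(segs$truth == 1 & segs$label == 0),
      tp = sum(segs$truth == 1 & segs$label == 1))
    cmSum <- cmSum + cm
    mm <- matrixMetrics(cm)
    foldRows[[f]] <- data.frame(fold = f, accuracy = .pct(mm["accuracy"]),
                                f1 = .pct(mm["f1"]))
  }
  mm <- matrixMetrics(cmSum)
  .makeAUReport("pain", data.frame(), do.call(rbind, foldRows),
                confusion = cmSum,
                summary = list(accuracy = .pct(mm["accuracy"]),
                               f1 = .pct(mm["f1"]),
                               precision = .pct(mm["precision"]),
                               recall = .pct(mm["recall"])))
}
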
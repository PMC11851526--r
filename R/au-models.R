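#' AUNet: fully-connected AU presence detector / intensity estimator
#'
#' A two-layer fully-connected network mapping a flattened, normalized
#' landmark frame (`3 * Ns` inputs) through a 128-unit ReLU hidden layer
#' to either 8 per-AU presence logits (logistic output, binary
#' cross-entropy) or 5 AU intensities (linear output, squared-error loss).
#'
#' @slot params List of weight arrays (`W1`, `b1`, `W2`, `b2`).
#' @slot outputType `"logistic"` (detection) or `"linear"` (intensity).
#' @slot auIds AU ids of the output units.
#' @slot config Resolved training configuration.
#' @slot history Per-epoch training-loss data frame.
#' @export
setClass("AUNet",
  representation(params = "list", outputType = "character",
                 auIds = "integer", config = "list",
                 history = "data.frame"))

setMethod("show", "AUNet", function(object) {
  cat(sprintf("AUNet (%s): %d -> %d -> %d, AUs %s; trained %d epochs\n",
              object@outputType, nrow(object@params$W1),
              ncol(object@params$W1), ncol(object@params$W2),
              paste(object@auIds, collapse = ","), nrow(object@history)))
})

#' AU network training configuration
#'
#' Defaults follow the reference training recipe: 128 hidden units,
#' batch size 64, up to 500 epochs, learning rate 0.01, Adam with moment
#' decay rates 0.9 / 0.999.
#'
#' @param inputSize Input dimension `3 * Ns` (1434 for the 478-point mesh).
#' @param hiddenUnits Hidden-layer width.
#' @param outputUnits 8 (detection) or 5 (intensity).
#' @param batchSize,maxEpochs,learningRate,adamBeta1,adamBeta2 Optimizer
#'   settings.
#' @param threshold Decision threshold for [binarizeAU()].
#' @param patience Early-stopping patience in epochs; 0 (default) disables
#'   early stopping.
#' @param seed Integer seed.
#' @return A list of class `AUDetectorConfig`.
#' @export
auDetectorConfig <- function(inputSize = 3L * 478L, hiddenUnits = 128L,
                             outputUnits = 8L, batchSize = 64L,
                             maxEpochs = 500L, learningRate = 0.01,
                             adamBeta1 = 0.9, adamBeta2 = 0.999,
                             threshold = 0.5, patience = 0L, seed = 1L) {
  stopifnot(inputSize > 0, hiddenUnits > 0, outputUnits > 0, batchSize > 0,
            maxEpochs > 0, learningRate > 0, learningRate < 1,
            adamBeta1 > 0, adamBeta1 < 1, adamBeta2 > 0, adamBeta2 < 1)
  structure(as.list(environment()), class = "AUDetectorConfig")
}

#' Train the AU presence detector
#'
#' Mini-batch Adam training of the two-layer network on normalized,
#' flattened frames. Each of the 8 output units is an independent
#' logistic detector for one AU of [auDetectIds()]; an AU with no
#' positive (or no negative) training frame is still trained but flagged
#' with a warning as unreliable.
#'
#' @param X `N x (3 Ns)` matrix of flattened normalized frames (see
#'   [frameMatrix()]).
#' @param Y `N x 8` 0/1 presence labels.
#' @param config An [auDetectorConfig()].
#' @param verbose Print per-epoch losses.
#' @return A trained [AUNet-class].
#' @export
trainAUDetector <- function(X, Y, config = auDetectorConfig(inputSize = ncol(X)),
                            verbose = FALSE) {
  stopifnot(nrow(X) == nrow(Y), ncol(Y) == config$outputUnits)
  pos <- colSums(Y); neg <- colSums(1 - Y)
  if (any(pos == 0 | neg == 0))
    .warnf("AU(s) %s have no positive or no negative training frames; those outputs are unreliable",
           paste(auDetectIds()[pos == 0 | neg == 0], collapse = ", "))
  fit <- .denseTrain(X, Y, "logistic", config$hiddenUnits,
                     config$learningRate, config$batchSize, config$maxEpochs,
                     config$adamBeta1, config$adamBeta2, config$seed,
                     patience = config$patience, verbose = verbose)
  config$inputSize <- ncol(X)
  new("AUNet", params = fit$params, outputType = "logistic",
      auIds = auDetectIds()[seq_len(config$outputUnits)], config = unclass(config),
      history = fit$history)
}

#' Predict AU presence scores
#'
#' @param model A trained detection [AUNet-class].
#' @param x A flattened frame vector, an `N x (3 Ns)` matrix of flattened
#'   frames, or an `Ns x 3` frame matrix.
#' @return Matrix of presence probabilities in `[0, 1]` (`N x 8`, columns
#'   named by AU id).
#' @export
predictAU <- function(model, x) {
  Z <- .aunetLogits(model, x)
  P <- stats::plogis(Z)
  colnames(P) <- as.character(model@auIds)
  P
}

.aunetLogits <- function(model, x) {
  if (is.matrix(x) && ncol(x) == 3L) x <- flattenFrame(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(model@params$W1))
    .stopf("painAU_invalid_input",
           "input size %d does not match model input size %d",
           ncol(x), nrow(model@params$W1))
  if (!is.null(model@params$center))
    x <- sweep(x, 2, model@params$center)
  .denseForward(model@params, x)$Z
}

#' Binarize AU scores at a decision threshold
#'
#' Elementwise `score >= threshold`.
#'
#' @param scores Probability vector/matrix from [predictAU()].
#' @param threshold Decision threshold (default 0.5).
#' @return 0/1 values with the shape of `scores`.
#' @export
binarizeAU <- function(scores, threshold = 0.5) {
  (scores >= threshold) + 0
}

#' Train the AU intensity estimator
#'
#' Same architecture as the detector, with a 5-unit linear output head
#' (AUs 6, 10, 12, 14, 17) trained under squared-error loss, matching
#' RMSE-based evaluation. Predictions are reported after clamping to the
#' FACS intensity range `[0, 5]`.
#'
#' @param X `N x (3 Ns)` matrix of flattened normalized frames.
#' @param Y `N x 5` intensity labels in `[0, 5]`.
#' @param config An [auDetectorConfig()] with `outputUnits = 5`.
#' @param verbose Print per-epoch losses.
#' @return A trained [AUNet-class].
#' @export
trainIntensityEstimator <- function(X, Y,
    config = auDetectorConfig(inputSize = ncol(X), outputUnits = 5L),
    verbose = FALSE) {
  if (is.null(Y) || nrow(Y) == 0)
    .stopf("painAU_contract_violation",
           "intensity training requires intensity-labeled frames")
  stopifnot(nrow(X) == nrow(Y), ncol(Y) == config$outputUnits)
  fit <- .denseTrain(X, Y, "linear", config$hiddenUnits,
                     config$learningRate, config$batchSize, config$maxEpochs,
                     config$adamBeta1, config$adamBeta2, config$seed,
                     patience = config$patience, verbose = verbose)
  config$inputSize <- ncol(X)
  new("AUNet", params = fit$params, outputType = "linear",
      auIds = auIntensityIds()[seq_len(config$outputUnits)], config = unclass(config),
      history = fit$history)
}

#' Predict AU intensities
#'
#' The linear head is unbounded; reported values are clamped to `[0, 5]`.
#'
#' @inheritParams predictAU
#' @param clamp Clamp to `[0, 5]` (default TRUE).
#' @return `N x 5` intensity matrix, columns named by AU id.
#' @export
predictIntensity <- function(model, x, clamp = TRUE) {
  Z <- .aunetLogits(model, x)
  if (clamp) Z <- pmin(pmax(Z, 0), 5)
  colnames(Z) <- as.character(model@auIds)
  Z
}

#' Round estimated intensities to FACS levels
#'
#' Nearest integer in `{0, ..., 5}`; ties (x.5) round half away from
#' zero; values outside the range clamp to it.
#'
#' @param values Numeric intensities.
#' @return Integer intensities in `{0..5}` with the shape of `values`.
#' @export
roundIntensity <- function(values) {
  r <- roundHalfUp(values, 0)
  r[] <- pmin(pmax(r, 0), 5)
  r
}

## ------------------------------------------------------------------
## Frame-matrix construction

#' Build network inputs/labels from a dataset
#'
#' Normalizes every (optionally strided) frame of every segment against
#' the template, flattens it, and stacks inputs and labels into matrices
#' ready for the AU networks.
#'
#' @param dataset A [LandmarkDataset-class].
#' @param template `Ns x 3` template for [normalizeFrame()]; `NULL` skips
#'   normalization (frames are flattened as-is).
#' @param frameStride Keep every `frameStride`-th frame (desk-scale
#'   subsampling; default 1 keeps all frames).
#' @param labels `"presence"`, `"intensity"` or `"none"`.
#' @return List with `X` (inputs), `Y` (labels or NULL), `subject`
#'   (per-row subject id), `segment` (per-row segment id).
#' @export
frameMatrix <- function(dataset, template = NULL, frameStride = 1L,
                        labels = c("presence", "intensity", "none")) {
  labels <- match.arg(labels)
  Xs <- list(); Ys <- list(); subj <- list(); segid <- list()
  for (seg in segments(dataset)) {
    idx <- seq(1L, nFrames(seg), by = frameStride)
    if (labels == "intensity" && !nrow(seg@auIntensity)) next
    if (labels == "presence" && !nrow(seg@auPresence)) next
    rows <- matrix(NA_real_, length(idx), 3L * nPoints(seg))
    for (j in seq_along(idx)) {
      fr <- getFrame(seg, idx[j])
      if (!is.null(template)) fr <- normalizeFrame(fr, template)
      rows[j, ] <- flattenFrame(fr)
    }
    Xs[[segmentId(seg)]] <- rows
    Ys[[segmentId(seg)]] <- switch(labels,
      presence = seg@auPresence[idx, , drop = FALSE],
      intensity = seg@auIntensity[idx, , drop = FALSE],
      none = NULL)
    subj[[segmentId(seg)]] <- rep(subjectId(seg), length(idx))
    segid[[segmentId(seg)]] <- rep(segmentId(seg), length(idx))
  }
  list(X = do.call(rbind, Xs),
       Y = if (labels == "none") NULL else do.call(rbind, Ys),
       subject = unlist(subj, use.names = FALSE),
       segment = unlist(segid, use.names = FALSE))
}
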
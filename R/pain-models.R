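#' Pain model configurations
#'
#' `painTransformerConfig()` defaults follow the reference recipe for the
#' Transformer-encoder pain classifier: 1024-dimensional linear
#' projection, 4 attention heads, 2 encoder layers, learning rate 1e-5,
#' batch size 16, up to 150 epochs, Adam moments 0.9/0.999. The MLP head
#' width (256) and dropout (0.1) are package choices. For the two-layer
#' LSTM baseline, `painLSTMConfig()` fixes hidden dimension 512 and
#' learning rate 1e-3 with the same batch size and epoch budget.
#'
#' @param naInput AU vector dimension per frame (8, or the all-AU count).
#' @param projectionDim Embedding dimension `d` (divisible by `numHeads`).
#' @param numHeads,numLayers Attention heads and encoder layers.
#' @param ffDim Position-wise feed-forward width (default `2 * d`).
#' @param mlpHidden Classification-head hidden units.
#' @param dropout Dropout rate on the head hidden layer during training.
#' @param learningRate,batchSize,maxEpochs,adamBeta1,adamBeta2 Optimizer.
#' @param seed Integer seed.
#' @return A config list of class `PainTransformerConfig`.
#' @export
painTransformerConfig <- function(naInput = 8L, projectionDim = 1024L,
                                  numHeads = 4L, numLayers = 2L,
                                  ffDim = 2L * projectionDim,
                                  mlpHidden = 256L, dropout = 0.1,
                                  learningRate = 1e-5, batchSize = 16L,
                                  maxEpochs = 150L, adamBeta1 = 0.9,
                                  adamBeta2 = 0.999, seed = 1L) {
  if (projectionDim %% numHeads != 0L)
    .stopf("painAU_invalid_input",
           "projectionDim (%d) must be divisible by numHeads (%d)",
           projectionDim, numHeads)
  structure(as.list(environment()), class = "PainTransformerConfig")
}

#' @rdname painTransformerConfig
#' @param hiddenDim LSTM hidden dimension.
#' @export
painLSTMConfig <- function(naInput = 8L, numLayers = 2L, hiddenDim = 512L,
                           learningRate = 1e-3, batchSize = 16L,
                           maxEpochs = 150L, adamBeta1 = 0.9,
                           adamBeta2 = 0.999, seed = 1L) {
  stopifnot(numLayers > 0, hiddenDim > 0, learningRate > 0, batchSize > 0)
  structure(as.list(environment()), class = "PainLSTMConfig")
}

#' PainTransformer / PainLSTM: trained temporal pain classifiers
#'
#' Produced by [trainPainModel()]; both map a fixed-length AU-vector
#' window to a pain probability via [predictPain()].
#'
#' @slot params Named list of weight arrays.
#' @slot config Resolved configuration.
#' @slot history Per-epoch training loss.
#' @export
setClass("PainTransformer",
  representation(params = "list", config = "list", history = "data.frame"))

#' @rdname PainTransformer-class
#' @export
setClass("PainLSTM",
  representation(params = "list", config = "list", history = "data.frame"))

setMethod("show", "PainTransformer", function(object) {
  cfg <- object@config
  cat(sprintf(
    "PainTransformer: %d AU inputs, projection %d, %d heads, %d encoder layers; trained %d epochs\n",
    cfg$naInput, cfg$projectionDim, cfg$numHeads, cfg$numLayers,
    nrow(object@history)))
})

setMethod("show", "PainLSTM", function(object) {
  cfg <- object@config
  cat(sprintf("PainLSTM: %d AU inputs, %d layers, hidden %d; trained %d epochs\n",
              cfg$naInput, cfg$numLayers, cfg$hiddenDim, nrow(object@history)))
})

## ------------------------------------------------------------------
## Windowing

#' Cut AU sequences into fixed-length windows
#'
#' Slides non-overlapping windows of `windowLength` frames (default 350,
#' about 14 s at 25 fps) over each segment's AU time series, adding one
#' right-aligned window when the leftover tail is at least
#' `tailFrac * windowLength` frames. Segments shorter than the window are
#' right-zero-padded with a padding mask; segments shorter than 10 frames
#' are skipped with a warning. Every window inherits the segment's label
#' and subject id.
#'
#' @param dataset A [LandmarkDataset-class] with class-labeled segments.
#' @param windowLength Frames per window.
#' @param stride Window stride (default `windowLength`).
#' @param tailFrac Minimum leftover-tail fraction that earns the extra
#'   right-aligned window.
#' @param auSource `"ground8"` (ground-truth presences of the 8 detector
#'   AUs), `"groundAll"` (all ground-truth AUs the dataset carries) or
#'   `"predicted8"` (per-frame detector scores — requires `detector` and
#'   `template`).
#' @param detector A trained detection [AUNet-class] (predicted8 only).
#' @param template Normalization template (predicted8 only).
#' @return List of windows; each is a list with `A` (`windowLength x Na`
#'   matrix), `valid` (padding mask), `y` (1 = pain), `subjectId`,
#'   `segmentId`.
#' @export
windowSegments <- function(dataset, windowLength = 350L,
                           stride = windowLength, tailFrac = 0.4,
                           auSource = c("ground8", "groundAll", "predicted8"),
                           detector = NULL, template = NULL) {
  auSource <- match.arg(auSource)
  if (auSource == "predicted8" && (is.null(detector) || is.null(template)))
    .stopf("painAU_missing_artifact",
           "auSource 'predicted8' requires a trained AU detector and a template")
  windows <- list()
  for (seg in segments(dataset)) {
    if (nFrames(seg) < 10L) {
      .warnf("segment %s has %d frames (< 10); skipped",
             segmentId(seg), nFrames(seg))
      next
    }
    series <- .auSeries(seg, auSource, detector, template)
    y <- as.integer(segmentClass(seg) == "pain")
    tn <- nrow(series)
    starts <- seq(1L, max(tn - windowLength + 1L, 1L), by = stride)
    tail <- tn - (max(starts) + windowLength - 1L)
    if (tail >= ceiling(tailFrac * windowLength))
      starts <- c(starts, tn - windowLength + 1L)
    for (s in starts) {
      e <- min(s + windowLength - 1L, tn)
      A <- matrix(0, windowLength, ncol(series))
      A[seq_len(e - s + 1L), ] <- series[s:e, , drop = FALSE]
      windows[[length(windows) + 1L]] <- list(
        A = A, valid = seq_len(windowLength) <= (e - s + 1L), y = y,
        subjectId = subjectId(seg), segmentId = segmentId(seg))
    }
  }
  windows
}

.auSeries <- function(seg, auSource, detector = NULL, template = NULL) {
  switch(auSource,
    ground8 = {
      if (!nrow(seg@auPresence))
        .stopf("painAU_invalid_input",
               "segment %s has no ground-truth presence labels", segmentId(seg))
      seg@auPresence
    },
    groundAll = {
      if (!nrow(seg@auAll))
        .stopf("painAU_invalid_input",
               "segment %s has no all-AU ground-truth labels", segmentId(seg))
      seg@auAll
    },
    predicted8 = {
      out <- matrix(NA_real_, nFrames(seg), length(auDetectIds()))
      for (t in seq_len(nFrames(seg)))
        out[t, ] <- predictAU(detector,
                              normalizeFrame(getFrame(seg, t), template))
      out
    })
}

## ------------------------------------------------------------------
## Training and prediction

#' Train a temporal pain classifier
#'
#' Trains either the Transformer-encoder classifier or the LSTM baseline
#' (chosen by the config class) on a set of AU windows with mini-batch
#' Adam under binary cross-entropy; class labels are other = 0, pain = 1.
#' Training windows must come from a training split that is
#' subject-disjoint from any evaluation data; a single-class window set
#' is a contract error.
#'
#' @param windows Window list from [windowSegments()].
#' @param config A [painTransformerConfig()] or [painLSTMConfig()].
#' @param verbose Print per-epoch losses.
#' @return A [PainTransformer-class] or [PainLSTM-class].
#' @export
trainPainModel <- function(windows, config, verbose = FALSE) {
  ys <- vapply(windows, function(w) w$y, numeric(1))
  if (length(unique(ys)) < 2L)
    .stopf("painAU_contract_violation",
           "training windows contain a single class; both pain and other are required")
  na <- ncol(windows[[1]]$A)
  if (na != config$naInput)
    .stopf("painAU_invalid_input",
           "windows carry %d AUs but config expects %d", na, config$naInput)
  isTf <- inherits(config, "PainTransformerConfig")
  gradFun <- if (isTf) {
    function(p, batch, seed) .tfBatchGrad(p, config, batch, dropSeed = seed)
  } else {
    function(p, batch, seed) .lstmBatchGrad(p, config, batch)
  }
  params <- if (isTf) .tfInit(config) else .lstmInit(config)
  st <- .adamInit(params)
  n <- length(windows)
  hist <- data.frame(epoch = integer(0), loss = numeric(0))
  for (ep in seq_len(config$maxEpochs)) {
    ord <- .withSeed(deriveSeed(config$seed, paste0("ep", ep)), sample.int(n))
    tot <- 0
    bi <- 0L
    for (start in seq(1L, n, by = config$batchSize)) {
      idx <- ord[start:min(start + config$batchSize - 1L, n)]
      bi <- bi + 1L
      lg <- gradFun(params, windows[idx],
                    deriveSeed(config$seed, sprintf("drop%d_%d", ep, bi)))
      up <- .adamStep(params, lg$grads, st, config$learningRate,
                      config$adamBeta1, config$adamBeta2)
      params <- up$params; st <- up$state
      tot <- tot + lg$loss * length(idx)
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = tot / n))
    if (verbose) message(sprintf("epoch %d: loss %.5f", ep, tot / n))
  }
  new(if (isTf) "PainTransformer" else "PainLSTM",
      params = params, config = unclass(config), history = hist)
}

#' Predict pain probability for AU windows
#'
#' Applies the trained classifier; the decision label is
#' `round(probability)` (threshold 0.5).
#'
#' @param model A [PainTransformer-class] or [PainLSTM-class].
#' @param windows One window or a list of windows from [windowSegments()].
#' @return Numeric vector of pain probabilities in `[0, 1]`.
#' @export
predictPain <- function(model, windows) {
  if (!is.null(windows$A)) windows <- list(windows)
  cfg <- model@config
  if (ncol(windows[[1]]$A) != cfg$naInput)
    .stopf("painAU_invalid_input",
           "window AU dimension %d does not match model input %d",
           ncol(windows[[1]]$A), cfg$naInput)
  vapply(windows, function(w) {
    if (is(model, "PainTransformer")) {
      fw <- .tfForward(w$A, model@params, cfg, w$valid)
      .tfHead(fw$Z, model@params, w$valid)$prob
    } else {
      .lstmPredictOne(model@params, cfg, w)
    }
  }, numeric(1))
}

.lstmPredictOne <- function(p, cfg, w) {
  X <- array(w$A, c(nrow(w$A), 1L, ncol(w$A)))
  layers <- .lstmForward(X, p, cfg)
  lv <- if (any(w$valid)) max(which(w$valid)) else 0L
  hfin <- if (lv > 0) layers[[cfg$numLayers]]$Hout[lv, 1L, ] else
    numeric(cfg$hiddenDim)
  stats::plogis(sum(hfin * p$head.Wo) + p$head.bo)
}

#' Encode an AU window with a trained Transformer
#'
#' Returns the `T x d` encoder representation (projection + positional
#' encoding + encoder layers), with padded positions masked out of
#' attention.
#'
#' @param model A [PainTransformer-class].
#' @param window One window from [windowSegments()].
#' @return `T x d` matrix.
#' @export
encodeSequence <- function(model, window) {
  if (ncol(window$A) != model@config$naInput)
    .stopf("painAU_invalid_input",
           "window AU dimension %d does not match model input %d",
           ncol(window$A), model@config$naInput)
  .tfForward(window$A, model@params, model@config, window$valid)$Z
}

#' Segment-level pain decisions from window probabilities
#'
#' Aggregates window-level decisions (`probability >= 0.5`) to one label
#' per segment by majority vote, ties deciding pain (the clinically
#' conservative direction).
#'
#' @param windows Window list.
#' @param probs Probabilities from [predictPain()].
#' @return Data frame: `segmentId`, `subjectId`, `truth`, `label`,
#'   `meanProb`.
#' @export
aggregateSegments <- function(windows, probs) {
  segId <- vapply(windows, `[[`, character(1), "segmentId")
  df <- data.frame(segmentId = segId,
                   subjectId = vapply(windows, `[[`, character(1), "subjectId"),
                   truth = vapply(windows, `[[`, numeric(1), "y"),
                   pred = as.integer(probs >= 0.5), prob = probs)
  out <- do.call(rbind, lapply(split(df, df$segmentId), function(d)
    data.frame(segmentId = d$segmentId[1], subjectId = d$subjectId[1],
               truth = d$truth[1],
               label = as.integer(mean(d$pred) >= 0.5),  # ties -> pain
               meanProb = mean(d$prob))))
  rownames(out) <- NULL
  out
}
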
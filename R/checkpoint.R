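## Model checkpoints: a documented HDF5 container holding the weight
## arrays under /weights plus a JSON architecture description attribute.

#' Save / load a trained model
#'
#' Works for [AUNet-class], [PainTransformer-class] and
#' [PainLSTM-class]. The container is HDF5: each weight array is a
#' dataset under `/weights` (named as in the parameter list), and the
#' file-level `architecture` attribute holds a JSON description (class,
#' config, AU ids). The weight round-trip is bit-exact.
#'
#' @param model A trained model object.
#' @param path Checkpoint path (`.h5`; overwritten).
#' @return `loadModel()` returns the reconstructed model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "AUNet") || is(model, "PainTransformer") ||
              is(model, "PainLSTM"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "weights")
  for (k in names(model@params))
    rhdf5::h5write(model@params[[k]], path, paste0("weights/", k))
  arch <- list(class = class(model)[1],
               config = unclass(model@config))
  if (is(model, "AUNet"))
    arch <- c(arch, list(outputType = model@outputType, auIds = model@auIds))
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(arch, auto_unbox = TRUE, digits = NA)),
    fid, "architecture")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path))
    .stopf("painAU_missing_artifact", "checkpoint not found: %s", path)
  arch <- jsonlite::fromJSON(
    rhdf5::h5readAttributes(path, "/")$architecture)
  idx <- rhdf5::h5ls(path)
  keys <- idx$name[idx$group == "/weights"]
  params <- stats::setNames(
    lapply(keys, function(k) {
      w <- rhdf5::h5read(path, paste0("weights/", k))
      if (is.array(w) && length(dim(w)) == 1L) w <- as.vector(w)
      w
    }), keys)
  cfg <- arch$config
  if (arch$class == "AUNet")
    new("AUNet", params = params, outputType = arch$outputType,
        auIds = as.integer(arch$auIds), config = cfg,
        history = data.frame())
  else
    new(arch$class, params = params, config = cfg, history = data.frame())
}

#' Export training history as CSV
#'
#' @param model A trained model with a loss history.
#' @param path CSV path (columns epoch, loss).
#' @export
exportTrainingLog <- function(model, path) {
  utils::write.csv(model@history, path, row.names = FALSE)
  invisible(path)
}

#' Export window predictions as CSV
#'
#' @param segDecisions Data frame from [aggregateSegments()].
#' @param path CSV path (`segment_id, subject_id, probability, label`).
#' @export
exportPredictions <- function(segDecisions, path) {
  utils::write.csv(
    data.frame(segment_id = segDecisions$segmentId,
               subject_id = segDecisions$subjectId,
               probability = segDecisions$meanProb,
               label = segDecisions$label),
    path, row.names = FALSE)
  invisible(path)
}
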
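## Experiment configuration: a nested YAML/JSON schema mirroring the
## module configs, with strict unknown-key rejection and a single global
## seed fanned out to module seeds via deriveSeed().

.configSchema <- function() {
  list(
    seed = 1L,
    outputDir = "painAU_output",
    simulation = formals(simulationConfig),
    augmentation = formals(augmentationSpec),
    au_detector = formals(auDetectorConfig),
    intensity = formals(auDetectorConfig),
    pain_transformer = formals(painTransformerConfig),
    pain_lstm = formals(painLSTMConfig),
    evaluation = list(kAU = 3L, kPain = 10L, windowLength = 350L,
                      stride = NULL, tailFrac = 0.4, frameStride = 1L,
                      auSource = "ground8", seed = NULL))
}

#' Load and resolve an experiment configuration
#'
#' Reads a YAML or JSON experiment file with nested sections
#' (`simulation`, `augmentation`, `au_detector`, `intensity`,
#' `pain_transformer`, `pain_lstm`, `evaluation`) plus global `seed` and
#' `outputDir`, fills defaults, rejects unknown keys (reporting the
#' offending key path), and fans the global seed out to per-module seeds
#' with [deriveSeed()]. Unset module seeds inherit from the global seed.
#'
#' @param path YAML/JSON file, or `NULL` for pure defaults.
#' @param overrides Named list merged over the file values.
#' @return Nested list of resolved settings (class `ExperimentConfig`).
#' @export
experimentConfig <- function(path = NULL, overrides = list()) {
  user <- if (is.null(path)) list() else {
    if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  user <- utils::modifyList(user, overrides)
  schema <- .configSchema()
  bad <- setdiff(names(user), names(schema))
  if (length(bad))
    .stopf("painAU_config_error", "unknown configuration key: %s", bad[1])
  out <- list(seed = as.integer(user$seed %||% schema$seed),
              outputDir = user$outputDir %||% schema$outputDir)
  for (sec in setdiff(names(schema), c("seed", "outputDir"))) {
    defaults <- lapply(schema[[sec]], function(d)
      if (is.language(d) || identical(d, quote(expr = ))) NULL else d)
    given <- user[[sec]] %||% list()
    badKey <- setdiff(names(given), names(defaults))
    if (length(badKey))
      .stopf("painAU_config_error", "unknown configuration key: %s.%s",
             sec, badKey[1])
    merged <- utils::modifyList(defaults, given)
    if (is.null(given$seed)) merged$seed <- deriveSeed(out$seed, sec)
    out[[sec]] <- merged
  }
  structure(out, class = "ExperimentConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the resolved configuration next to an output
#'
#' Every artifact-producing run records the fully resolved configuration
#' (defaults filled, seeds fanned out) so any experiment is reproducible
#' from the emitted file alone.
#'
#' @param config An `ExperimentConfig`.
#' @param path Output JSON path.
#' @export
writeResolvedConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

## Resolve a config section into the matching constructor call.
.sectionConfig <- function(config, sec) {
  args <- Filter(Negate(is.null), config[[sec]])
  ctor <- switch(sec,
    simulation = simulationConfig, augmentation = augmentationSpec,
    au_detector = auDetectorConfig, intensity = auDetectorConfig,
    pain_transformer = painTransformerConfig, pain_lstm = painLSTMConfig)
  do.call(ctor, args)
}
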
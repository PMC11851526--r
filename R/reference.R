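#' Published reference benchmark tables
#'
#' Reference evaluation results for landmark-based AU detection and pain
#' classification on the BP4D+ pain benchmark, shipped as plain CSV under
#' `inst/extdata/reference/`. They serve two purposes: sanity-checking
#' the metric implementations against the printed arithmetic (row
#' averages, confusion-matrix-derived accuracy) and putting the package's
#' synthetic-data results in context.
#'
#' Components:
#' \describe{
#'   \item{auF1}{Per-AU F1 (\%) for the 8 primary AUs, by method.}
#'   \item{rareAuF1}{Per-AU F1 (\%) for the 7 rare AUs, with and without
#'     training-set augmentation.}
#'   \item{intensityError}{Per-AU intensity RMSE/MAE, by method.}
#'   \item{painPerformance}{Pain-detection F1/accuracy (\%) by model and
#'     AU source (predicted 8, ground-truth 8, all ground-truth AUs).}
#'   \item{painConfusion}{Segment-level confusion-matrix counts summed
#'     over the 10 folds of the predicted-8-AU Transformer run.}
#'   \item{datasetCounts}{Frame/segment bookkeeping of the benchmark
#'     corpus (140 subjects; 1 pain + 3 other segments each).}
#' }
#'
#' @return Named list of data frames.
#' @examples
#' ref <- referenceBenchmark()
#' rowMeans(ref$auF1[ref$auF1$method == "landmark_fcn_mesh478", -1])
#' @export
referenceBenchmark <- function() {
  dir <- system.file("extdata", "reference", package = "painAU",
                     mustWork = TRUE)
  rd <- function(f) utils::read.csv(file.path(dir, f), check.names = FALSE)
  list(auF1 = rd("au_f1.csv"),
       rareAuF1 = rd("rare_au_f1.csv"),
       intensityError = rd("intensity_error.csv"),
       painPerformance = rd("pain_performance.csv"),
       painConfusion = rd("pain_confusion.csv"),
       datasetCounts = rd("dataset_counts.csv"))
}
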
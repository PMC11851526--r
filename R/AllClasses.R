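#' LandmarkSequence: one subject segment of 3D face landmarks
#'
#' The anonymized unit of exchange: a `T x Ns x 3` array of 3D face
#' landmark coordinates over `T` frames, with identity metadata and
#' (optionally) per-frame action-unit labels. Coordinates follow the
#' common face-mesh convention: x rightward in the subject's image,
#' y downward, z toward the camera.
#'
#' Slots:
#' \describe{
#'   \item{coords}{`T x Ns x 3` numeric array, all finite.}
#'   \item{frameRate}{Frames per second (> 0; default 25).}
#'   \item{subjectId, segmentId}{Opaque identifier strings.}
#'   \item{segmentClass}{`"pain"`, `"other"` or `"unlabeled"`.}
#'   \item{auPresence}{`T x 8` 0/1 matrix over [auDetectIds()], or a
#'     `0 x 0` matrix when the segment carries no presence labels.}
#'   \item{auIntensity}{`T x 5` matrix in `[0, 5]` over
#'     [auIntensityIds()], or `0 x 0` when intensity-unlabeled.}
#'   \item{auAll}{Optional `T x K` 0/1 matrix of ground-truth presences
#'     for every AU the source carries (columns named by AU id); used by
#'     the all-AU pain-detection mode.}
#'   \item{metadata}{Free-form list (e.g. elicited emotion, provenance).}
#' }
#'
#' @aliases coords nFrames nPoints topology frameRate subjectId segmentId
#'   segmentClass auPresence auIntensity
#' @export
setClass("LandmarkSequence",
  representation(coords = "array", frameRate = "numeric",
                 subjectId = "character", segmentId = "character",
                 segmentClass = "character", auPresence = "matrix",
                 auIntensity = "matrix", auAll = "matrix",
                 metadata = "list"))

setValidity("LandmarkSequence", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be a T x Ns x 3 array")
  if (d[1] < 1L) return("sequence must contain at least one frame (T >= 1)")
  if (!all(is.finite(object@coords)))
    return("coords must be finite")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    return("frameRate must be a single positive number")
  if (!object@segmentClass %in% c("pain", "other", "unlabeled"))
    return("segmentClass must be 'pain', 'other' or 'unlabeled'")
  if (nrow(object@auPresence) > 0L) {
    if (nrow(object@auPresence) != d[1] || ncol(object@auPresence) != 8L)
      return("auPresence must be T x 8")
    if (!all(object@auPresence %in% c(0, 1)))
      return("auPresence values must be 0/1")
  }
  if (nrow(object@auIntensity) > 0L) {
    if (nrow(object@auIntensity) != d[1] || ncol(object@auIntensity) != 5L)
      return("auIntensity must be T x 5")
    if (any(object@auIntensity < 0 | object@auIntensity > 5))
      return("auIntensity values must lie in [0, 5]")
  }
  if (nrow(object@auAll) > 0L && nrow(object@auAll) != d[1])
    return("auAll must have one row per frame")
  TRUE
})

#' Construct a LandmarkSequence
#'
#' @param coords `T x Ns x 3` numeric array (a single `Ns x 3` frame is
#'   promoted to `T = 1`).
#' @param frameRate Frames per second.
#' @param subjectId,segmentId Identifier strings.
#' @param segmentClass `"pain"`, `"other"` or `"unlabeled"`.
#' @param auPresence,auIntensity,auAll Optional label matrices (see the
#'   class description).
#' @param metadata Free-form list.
#' @return A [LandmarkSequence-class] object.
#' @examples
#' seq1 <- LandmarkSequence(array(rnorm(10 * 83 * 3), c(10, 83, 3)),
#'                          subjectId = "S1", segmentId = "S1_seg1")
#' nFrames(seq1); topology(seq1)
#' @export
LandmarkSequence <- function(coords, frameRate = 25, subjectId = "unknown",
                             segmentId = "seg", segmentClass = "unlabeled",
                             auPresence = NULL, auIntensity = NULL,
                             auAll = NULL, metadata = list()) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  empty <- matrix(numeric(0), 0, 0)
  new("LandmarkSequence", coords = coords, frameRate = frameRate,
      subjectId = as.character(subjectId), segmentId = as.character(segmentId),
      segmentClass = segmentClass,
      auPresence = if (is.null(auPresence)) empty else as.matrix(auPresence),
      auIntensity = if (is.null(auIntensity)) empty else as.matrix(auIntensity),
      auAll = if (is.null(auAll)) empty else as.matrix(auAll),
      metadata = metadata)
}

#' @rdname LandmarkSequence-class
setMethod("coords", "LandmarkSequence", function(x) x@coords)
#' @rdname LandmarkSequence-class
setMethod("nFrames", "LandmarkSequence", function(x) dim(x@coords)[1])
#' @rdname LandmarkSequence-class
setMethod("nPoints", "LandmarkSequence", function(x) dim(x@coords)[2])
#' @rdname LandmarkSequence-class
setMethod("topology", "LandmarkSequence",
          function(x) .topologyFromN(dim(x@coords)[2]))
#' @rdname LandmarkSequence-class
setMethod("frameRate", "LandmarkSequence", function(x) x@frameRate)
#' @rdname LandmarkSequence-class
setMethod("subjectId", "LandmarkSequence", function(x) x@subjectId)
#' @rdname LandmarkSequence-class
setMethod("segmentId", "LandmarkSequence", function(x) x@segmentId)
#' @rdname LandmarkSequence-class
setMethod("segmentClass", "LandmarkSequence", function(x) x@segmentClass)
#' @rdname LandmarkSequence-class
setMethod("auPresence", "LandmarkSequence", function(x) x@auPresence)
#' @rdname LandmarkSequence-class
setMethod("auIntensity", "LandmarkSequence", function(x) x@auIntensity)

setMethod("show", "LandmarkSequence", function(object) {
  cat(sprintf(
    "LandmarkSequence %s (subject %s, class %s)\n  %d frames x %d points @ %g fps (%s)%s%s\n",
    object@segmentId, object@subjectId, object@segmentClass,
    nFrames(object), nPoints(object), object@frameRate, topology(object),
    if (nrow(object@auPresence)) ", AU presence labels" else "",
    if (nrow(object@auIntensity)) ", AU intensity labels" else ""))
})

## Extract one frame as an Ns x 3 matrix.
#' @rdname LandmarkSequence-class
#' @param i Frame index.
#' @export
getFrame <- function(x, i) {
  stopifnot(is(x, "LandmarkSequence"), i >= 1, i <= nFrames(x))
  matrix(x@coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' MirrorMap: left/right landmark correspondence
#'
#' Records, for a fixed topology, which landmark indices swap under a
#' horizontal (left/right) mirror of the face and which lie on the
#' midline. The induced index permutation is an involution.
#'
#' @slot pairs Integer matrix with columns `left`, `right`.
#' @slot midline Integer vector of self-paired indices.
#' @slot nPoints Total number of landmarks.
#' @export
setClass("MirrorMap",
  representation(pairs = "matrix", midline = "integer", nPoints = "integer"))

setValidity("MirrorMap", function(object) {
  idx <- c(object@pairs[, 1], object@pairs[, 2], object@midline)
  if (length(idx) != object@nPoints || anyDuplicated(idx) ||
      !setequal(idx, seq_len(object@nPoints)))
    return("every landmark index must appear exactly once across pairs and midline")
  p <- mirrorPermutation(object)
  if (!identical(p[p], seq_len(object@nPoints)))
    return("mirror permutation must be an involution")
  TRUE
})

#' @rdname MirrorMap-class
#' @param pairs Two-column integer matrix of (left, right) indices.
#' @param midline Integer vector of midline indices.
#' @param nPoints Total landmark count (defaults to the indices present).
#' @export
MirrorMap <- function(pairs, midline = integer(0), nPoints = NULL) {
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("left", "right")))
  midline <- as.integer(midline)
  if (is.null(nPoints)) nPoints <- length(midline) + 2L * nrow(pairs)
  new("MirrorMap", pairs = pairs, midline = midline,
      nPoints = as.integer(nPoints))
}

#' @rdname MirrorMap-class
#' @param map A `MirrorMap`.
#' @return `mirrorPermutation()`: the integer permutation sending each
#'   landmark index to its mirrored counterpart.
#' @export
mirrorPermutation <- function(map) {
  p <- seq_len(map@nPoints)
  p[map@pairs[, 1]] <- map@pairs[, 2]
  p[map@pairs[, 2]] <- map@pairs[, 1]
  p
}

setMethod("show", "MirrorMap", function(object) {
  cat(sprintf("MirrorMap: %d landmarks (%d mirrored pairs, %d midline)\n",
              object@nPoints, nrow(object@pairs), length(object@midline)))
})

#' DeformationBasis: per-AU landmark displacement fields
#'
#' The simulator's forward model: for each action unit a smooth, localized
#' `Ns x 3` displacement field over the template mesh. A frame at AU
#' intensities I is rendered as
#' `template + sum_k (I_k / 5) * field_k` (plus pose and noise).
#'
#' @slot template Centered `Ns x 3` template mesh.
#' @slot fields Named list (by AU id) of `Ns x 3` displacement fields.
#' @slot masks Named list of per-AU landmark weights in `[0, 1]`; each
#'   field is zero outside its mask's support.
#' @slot gain Maximal landmark displacement (template units) at intensity 5.
#' @export
setClass("DeformationBasis",
  representation(template = "matrix", fields = "list", masks = "list",
                 gain = "numeric"))

setValidity("DeformationBasis", function(object) {
  ns <- nrow(object@template)
  for (k in names(object@fields)) {
    f <- object@fields[[k]]
    if (!is.matrix(f) || nrow(f) != ns || ncol(f) != 3L)
      return(sprintf("field for AU %s must be Ns x 3", k))
    m <- object@masks[[k]]
    if (is.null(m) || length(m) != ns || any(m < 0 | m > 1))
      return(sprintf("mask for AU %s must be Ns weights in [0,1]", k))
    if (any(rowSums(abs(f))[m == 0] > 0))
      return(sprintf("field for AU %s is nonzero outside its mask support", k))
  }
  TRUE
})

setMethod("show", "DeformationBasis", function(object) {
  cat(sprintf("DeformationBasis: %d AU fields over %d landmarks (gain %.3g)\n  AUs: %s\n",
              length(object@fields), nrow(object@template), object@gain,
              paste(names(object@fields), collapse = ", ")))
})

#' ActivationTimecourse: ground-truth AU intensities over time
#'
#' Smooth per-frame AU intensities in `[0, 5]` for one simulated segment,
#' with bounded frame-to-frame change (at most 1 intensity unit).
#'
#' @slot intensities `T x K` matrix in `[0, 5]`, columns named by AU id.
#' @slot auIds Integer AU ids (column order).
#' @slot exprClass Expression class: `"pain"`, `"happiness"`,
#'   `"embarrassment"` or `"fear"`.
#' @slot frameRate Frames per second.
#' @export
setClass("ActivationTimecourse",
  representation(intensities = "matrix", auIds = "integer",
                 exprClass = "character", frameRate = "numeric"))

setValidity("ActivationTimecourse", function(object) {
  x <- object@intensities
  if (ncol(x) != length(object@auIds))
    return("one column per AU id required")
  if (any(x < 0 | x > 5)) return("intensities must lie in [0, 5]")
  if (nrow(x) > 1 && max(abs(diff(x))) > 1 + 1e-9)
    return("frame-to-frame intensity change must not exceed 1")
  TRUE
})

setMethod("show", "ActivationTimecourse", function(object) {
  act <- object@auIds[apply(object@intensities, 2, max) >= 1]
  cat(sprintf("ActivationTimecourse (%s): %d frames, active AUs: %s\n",
              object@exprClass, nrow(object@intensities),
              paste(act, collapse = ", ")))
})

#' LandmarkDataset: a collection of landmark segments with a manifest
#'
#' In-memory form of the package's dataset container: a list of
#' [LandmarkSequence-class] segments plus a manifest data frame
#' (`segmentId`, `subjectId`, `segmentClass`, `split`, `provenance`).
#' [writeLandmarkDataset()] / [readLandmarkDataset()] persist it as HDF5
#' with a JSON manifest.
#'
#' @aliases segments manifest
#' @slot segments Named list of `LandmarkSequence`.
#' @slot manifest One row per segment.
#' @export
setClass("LandmarkDataset",
  representation(segments = "list", manifest = "data.frame"))

setValidity("LandmarkDataset", function(object) {
  ids <- vapply(object@segments, segmentId, character(1))
  if (anyDuplicated(ids)) return("segment ids must be unique")
  if (nrow(object@manifest) != length(object@segments))
    return("manifest must have one row per segment")
  if (!all(object@manifest$segmentId == ids))
    return("manifest rows must align with segments")
  TRUE
})

#' @rdname LandmarkDataset-class
#' @param segs List of [LandmarkSequence-class] objects.
#' @param split Split tag recycled over segments (`"train"`, `"test"` or
#'   `"none"`).
#' @export
LandmarkDataset <- function(segs, split = "none") {
  ids <- vapply(segs, segmentId, character(1))
  names(segs) <- ids
  man <- data.frame(
    segmentId = ids,
    subjectId = vapply(segs, subjectId, character(1)),
    segmentClass = vapply(segs, segmentClass, character(1)),
    split = rep_len(split, length(segs)),
    provenance = rep_len("original", length(segs)),
    stringsAsFactors = FALSE, row.names = NULL)
  new("LandmarkDataset", segments = segs, manifest = man)
}

#' @rdname LandmarkDataset-class
setMethod("segments", "LandmarkDataset", function(x) x@segments)
#' @rdname LandmarkDataset-class
setMethod("manifest", "LandmarkDataset", function(x) x@manifest)

setMethod("show", "LandmarkDataset", function(object) {
  m <- object@manifest
  cat(sprintf("LandmarkDataset: %d segments, %d subjects (%s)\n",
              nrow(m), length(unique(m$subjectId)),
              paste(sprintf("%s: %d", names(table(m$segmentClass)),
                            table(m$segmentClass)), collapse = ", ")))
})

#' @rdname LandmarkDataset-class
#' @param x A `LandmarkDataset`.
#' @param subjects Subject ids to keep.
#' @param split New split tag for the subset.
#' @return `subsetBySubject()`: a new dataset restricted to `subjects`.
#' @export
subsetBySubject <- function(x, subjects, split = NULL) {
  keep <- x@manifest$subjectId %in% subjects
  out <- new("LandmarkDataset", segments = x@segments[keep],
             manifest = x@manifest[keep, , drop = FALSE])
  if (!is.null(split)) out@manifest$split <- split
  out@manifest <- `rownames<-`(out@manifest, NULL)
  out
}

#' Content hash of a dataset
#'
#' Canonical md5 hash of every segment's arrays and metadata; two datasets
#' simulated with the same seed hash identically, independent of any
#' container-level write metadata.
#'
#' @param x A [LandmarkDataset-class].
#' @return md5 hex string.
#' @export
datasetHash <- function(x) {
  .objectHash(lapply(segments(x), function(s)
    list(coords = s@coords, p = s@auPresence, i = s@auIntensity,
         a = s@auAll, meta = c(s@subjectId, s@segmentId, s@segmentClass,
                               as.character(s@frameRate)))))
}

#' FoldAssignment: subject-level cross-validation folds
#'
#' @slot k Number of folds.
#' @slot mapping Named integer vector: subject id -> fold index; fold
#'   sizes differ by at most one and each subject appears exactly once
#'   (the subject-independence contract).
#' @slot seed Seed that produced the assignment.
#' @export
setClass("FoldAssignment",
  representation(k = "integer", mapping = "integer", seed = "integer"))

setValidity("FoldAssignment", function(object) {
  if (anyDuplicated(names(object@mapping)))
    return("each subject must appear exactly once")
  tab <- tabulate(object@mapping, object@k)
  if (max(tab) - min(tab) > 1L) return("fold sizes must differ by at most 1")
  TRUE
})

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d subjects in %d folds (sizes %s)\n",
              length(object@mapping), object@k,
              paste(tabulate(object@mapping, object@k), collapse = "/")))
})
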
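#' Augmentation specification
#'
#' Landmark-space analogues of classic image augmentations used to
#' oversample rare-AU frames: horizontal flip, small 3D rotations,
#' framing jitter (translation + scale — the landmark-visible effect of a
#' crop, which cannot remove points because the networks need all
#' `3 * Ns` inputs) and shear ("linear distortion"). All ranges are
#' symmetric about the identity, so the expected transform is the
#' identity and a zero-range spec is exactly the identity.
#'
#' @param enableFlip Allow mirrored copies (requires a [MirrorMap-class]).
#' @param rotationRange Max rotation per axis, degrees (default 15).
#' @param translationRange Max translation per axis as a fraction of the
#'   frame scale (default 0.05).
#' @param scaleRange Uniform scale factor range (default `c(0.9, 1.1)`).
#' @param shearRange Max off-diagonal magnitude of the shear matrix
#'   (default 0.1).
#' @param seed Integer seed making the transform stream reproducible.
#' @return A list of class `AugmentationSpec`.
#' @export
augmentationSpec <- function(enableFlip = TRUE, rotationRange = 15,
                             translationRange = 0.05,
                             scaleRange = c(0.9, 1.1), shearRange = 0.1,
                             seed = 1L) {
  stopifnot(rotationRange >= 0, translationRange >= 0, shearRange >= 0,
            length(scaleRange) == 2, scaleRange[1] <= scaleRange[2])
  structure(list(enableFlip = enableFlip, rotationRange = rotationRange,
                 translationRange = translationRange,
                 scaleRange = scaleRange, shearRange = shearRange,
                 seed = as.integer(seed)),
            class = "AugmentationSpec")
}

#' Horizontal flip of a landmark sequence
#'
#' Mirrors the face about the vertical midline: x-coordinates are negated
#' and landmark indices are permuted by the topology's [MirrorMap-class],
#' so the flipped frame is a valid mesh of the same topology. AU labels
#' are unchanged (the label schema is bilateral). `hflip` is an exact
#' involution.
#'
#' @param seq A [LandmarkSequence-class].
#' @param mirror The topology's [MirrorMap-class].
#' @return The mirrored sequence.
#' @export
hflip <- function(seq, mirror) {
  if (missing(mirror) || !is(mirror, "MirrorMap"))
    .stopf("painAU_capability_error",
           "horizontal flip requires a MirrorMap for this topology")
  if (mirror@nPoints != nPoints(seq))
    .stopf("painAU_invalid_input",
           "MirrorMap is for %d points but sequence has %d",
           mirror@nPoints, nPoints(seq))
  p <- mirrorPermutation(mirror)
  out <- seq@coords[, p, , drop = FALSE]
  out[, , 1] <- -out[, , 1]
  initialize(seq, coords = out)
}

## Draw one rotation+scale+shear+translation transform from a spec.
.drawTransform <- function(spec, scaleRef) {
  ang <- stats::runif(3, -spec$rotationRange, spec$rotationRange) * pi / 180
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  S <- diag(3)
  S[upper.tri(S) | lower.tri(S)] <-
    stats::runif(6, -spec$shearRange, spec$shearRange)
  sc <- stats::runif(1, spec$scaleRange[1], spec$scaleRange[2])
  tr <- stats::runif(3, -spec$translationRange, spec$translationRange) * scaleRef
  list(M = sc * (Rz %*% Ry %*% Rx) %*% S, t = tr)
}

#' Random similarity + shear transform of a sequence
#'
#' Samples one transform per segment (not per frame, preserving temporal
#' coherence) — rotation, uniform scale, shear, translation — and applies
#' it to every frame. With shear off and unit scale the transform is a
#' rigid isometry and all pairwise inter-landmark distances are preserved.
#'
#' @param seq A [LandmarkSequence-class].
#' @param spec An [augmentationSpec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return Transformed sequence.
#' @export
randomSimilarityShear <- function(seq, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "AugmentationSpec"))
  f1 <- getFrame(seq, 1L)
  scaleRef <- mean(sqrt(rowSums(sweep(f1, 2, colMeans(f1))^2)))
  tf <- .withSeed(seed, .drawTransform(spec, scaleRef))
  out <- seq@coords
  for (t in seq_len(nFrames(seq)))
    out[t, , ] <- getFrame(seq, t) %*% t(tf$M) +
      matrix(tf$t, nPoints(seq), 3, byrow = TRUE)
  initialize(seq, coords = out)
}

#' Oversample rare-AU frames in a training split
#'
#' For every segment of a *training-tagged* dataset, the frames positive
#' for any target AU are duplicated `copies` times; each copy is one new
#' segment carrying those frames under an independently drawn
#' [randomSimilarityShear()] transform (optionally mirrored), with labels
#' copied verbatim and provenance recorded in the manifest. Calling this
#' on a test-tagged split is a contract violation (it would leak
#' synthetic copies into evaluation).
#'
#' @param dataset A [LandmarkDataset-class] whose manifest is tagged
#'   `split = "train"`.
#' @param targetAUs AU ids (subset of [auDetectIds()] columns by id, or of
#'   the `auAll` ids) whose positive frames are oversampled.
#' @param copies Copies per positive frame (default 4).
#' @param spec An [augmentationSpec()].
#' @param mirror Optional [MirrorMap-class] enabling flipped copies.
#' @return The augmented dataset.
#' @export
oversampleRare <- function(dataset, targetAUs, copies = 4L,
                           spec = augmentationSpec(), mirror = NULL) {
  man <- manifest(dataset)
  if (any(man$split == "test"))
    .stopf("painAU_contract_violation",
           "oversampleRare called on a test-tagged split; augmentation is restricted to training data")
  if (!all(man$split == "train"))
    .stopf("painAU_contract_violation",
           "dataset must be tagged split = 'train' before oversampling")
  if (copies < 1L) return(dataset)
  newSegs <- list(); prov <- character(0)
  for (seg in segments(dataset)) {
    pos <- .positiveFrames(seg, targetAUs)
    if (!length(pos)) next
    for (k in seq_len(copies)) {
      sd <- deriveSeed(spec$seed, paste0(segmentId(seg), "/copy", k))
      sub <- .subsetFrames(seg, pos)
      sub@segmentId <- sprintf("%s_aug%d", segmentId(seg), k)
      flip <- spec$enableFlip && !is.null(mirror) &&
        .withSeed(deriveSeed(sd, "flip"), stats::runif(1)) < 0.5
      if (flip) sub <- hflip(sub, mirror)
      sub <- randomSimilarityShear(sub, spec, seed = sd)
      newSegs[[length(newSegs) + 1L]] <- sub
      prov <- c(prov, sprintf("augmented:%s", segmentId(seg)))
    }
  }
  if (!length(newSegs)) return(dataset)
  aug <- LandmarkDataset(c(segments(dataset), newSegs), split = "train")
  aug@manifest$provenance <- c(man$provenance, prov)
  validObject(aug)
  aug
}

## Frames of `seg` positive for any of `targetAUs` (detection schema
## first, falling back to the all-AU ground-truth matrix).
.positiveFrames <- function(seg, targetAUs) {
  det <- match(targetAUs, auDetectIds())
  if (!anyNA(det) && nrow(seg@auPresence))
    return(which(rowSums(seg@auPresence[, det, drop = FALSE]) > 0))
  if (nrow(seg@auAll)) {
    cols <- match(as.character(targetAUs), colnames(seg@auAll))
    if (anyNA(cols))
      .stopf("painAU_invalid_input", "AU id(s) %s not in the label space",
             paste(targetAUs[is.na(cols)], collapse = ", "))
    return(which(rowSums(seg@auAll[, cols, drop = FALSE]) > 0))
  }
  .stopf("painAU_invalid_input", "segment %s carries no presence labels",
         segmentId(seg))
}

.subsetFrames <- function(seg, idx) {
  initialize(seg,
    coords = seg@coords[idx, , , drop = FALSE],
    auPresence = if (nrow(seg@auPresence))
      seg@auPresence[idx, , drop = FALSE] else seg@auPresence,
    auIntensity = if (nrow(seg@auIntensity))
      seg@auIntensity[idx, , drop = FALSE] else seg@auIntensity,
    auAll = if (nrow(seg@auAll)) seg@auAll[idx, , drop = FALSE] else seg@auAll)
}
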
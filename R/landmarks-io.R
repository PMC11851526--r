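#' Similarity-Procrustes normalization of a landmark frame
#'
#' Removes rigid pose and global scale from a frame: the centroid is
#' translated to the origin, the frame is isotropically scaled so its mean
#' point-to-centroid distance matches the (centered) template's, and the
#' least-squares rigid rotation (no reflection; Kabsch solution) onto the
#' template is applied. The output is invariant, within `1e-6`, to any
#' rigid transform plus uniform scaling of the input, which makes the
#' downstream AU detector pose-invariant.
#'
#' @param frame `Ns x 3` landmark matrix (or a 1-frame
#'   [LandmarkSequence-class]).
#' @param template `Ns x 3` template with the same topology. Templates
#'   produced by [makeTemplate()] are already centered and unit-scale.
#' @return Normalized `Ns x 3` matrix in the template's frame.
#' @examples
#' tpl <- makeTemplate("bp4d83")
#' max(abs(normalizeFrame(tpl, tpl) - tpl)) < 1e-9
#' @export
normalizeFrame <- function(frame, template) {
  if (is(frame, "LandmarkSequence")) frame <- getFrame(frame, 1L)
  if (!is.matrix(frame) || ncol(frame) != 3L)
    .stopf("painAU_invalid_input", "frame must be an Ns x 3 matrix")
  if (nrow(frame) != nrow(template))
    .stopf("painAU_invalid_input",
           "topology mismatch: frame has %d points, template %d",
           nrow(frame), nrow(template))
  X <- sweep(frame, 2, colMeans(frame))
  rx <- mean(sqrt(rowSums(X^2)))
  if (rx < 1e-12)
    .stopf("painAU_degenerate_geometry",
           "degenerate frame: all landmarks coincide")
  Yt <- sweep(template, 2, colMeans(template))
  ry <- mean(sqrt(rowSums(Yt^2)))
  X <- X * (ry / rx)
  ## Kabsch: rotation minimizing ||X R - Yt||_F with det(R) = +1
  s <- svd(crossprod(X, Yt))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  out <- X %*% R
  dimnames(out) <- list(NULL, c("x", "y", "z"))
  out
}

#' Normalize every frame of a sequence against a template
#'
#' @param seq A [LandmarkSequence-class].
#' @inheritParams normalizeFrame
#' @return The sequence with each frame normalized.
#' @export
normalizeSequence <- function(seq, template) {
  out <- seq@coords
  for (t in seq_len(nFrames(seq)))
    out[t, , ] <- normalizeFrame(getFrame(seq, t), template)
  initialize(seq, coords = out)
}

#' Flatten a landmark frame to the network input vector
#'
#' Deterministic ordering `(x0, y0, z0, x1, y1, z1, ...)`, giving the
#' `3 * Ns` input the AU networks consume (1434 values for the 478-point
#' mesh, 249 for the 83-point topology). `unflattenFrame()` is the exact
#' inverse.
#'
#' @param frame `Ns x 3` matrix.
#' @return Numeric vector of length `3 * Ns`.
#' @export
flattenFrame <- function(frame) {
  if (is(frame, "LandmarkSequence")) frame <- getFrame(frame, 1L)
  as.vector(t(frame))
}

#' @rdname flattenFrame
#' @param v Numeric vector of length `3 * Ns`.
#' @export
unflattenFrame <- function(v) {
  matrix(v, ncol = 3L, byrow = TRUE, dimnames = list(NULL, c("x", "y", "z")))
}

## ------------------------------------------------------------------
## HDF5 dataset container

#' Write / read the landmark dataset container
#'
#' The on-disk container is HDF5: one group per segment under `/segments`
#' holding `landmarks` (`T x Ns x 3`), `au_presence` (`T x 8`),
#' `au_intensity` (`T x 5`, absent when the segment is intensity-unlabeled)
#' and `au_all` (optional `T x K`), with `subject_id`, `segment_class` and
#' `frame_rate` attributes. A JSON manifest is written alongside
#' (`<path>.manifest.json`). The array round-trip is bit-exact.
#'
#' @param dataset A [LandmarkDataset-class].
#' @param path Path of the `.h5` container to create (overwritten).
#' @return `writeLandmarkDataset()` invisibly returns the manifest;
#'   `readLandmarkDataset()` returns the reconstructed
#'   [LandmarkDataset-class].
#' @export
writeLandmarkDataset <- function(dataset, path) {
  stopifnot(is(dataset, "LandmarkDataset"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "segments")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  for (seg in segments(dataset)) {
    g <- paste0("segments/", segmentId(seg))
    rhdf5::h5createGroup(fid, g)
    rhdf5::h5write(seg@coords, fid, paste0(g, "/landmarks"))
    if (nrow(seg@auPresence))
      rhdf5::h5write(seg@auPresence, fid, paste0(g, "/au_presence"))
    if (nrow(seg@auIntensity))
      rhdf5::h5write(seg@auIntensity, fid, paste0(g, "/au_intensity"))
    if (nrow(seg@auAll)) {
      rhdf5::h5write(seg@auAll, fid, paste0(g, "/au_all"))
      rhdf5::h5write(as.integer(colnames(seg@auAll)), fid,
                     paste0(g, "/au_all_ids"))
    }
    gid <- rhdf5::H5Gopen(fid, g)
    rhdf5::h5writeAttribute(subjectId(seg), gid, "subject_id")
    rhdf5::h5writeAttribute(segmentClass(seg), gid, "segment_class")
    rhdf5::h5writeAttribute(frameRate(seg), gid, "frame_rate")
    rhdf5::H5Gclose(gid)
  }
  man <- manifest(dataset)
  jsonlite::write_json(
    list(topology = topology(segments(dataset)[[1]]),
         label_schema = list(detection = auDetectIds(),
                             intensity = auIntensityIds()),
         segments = man),
    paste0(path, ".manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(man)
}

#' @rdname writeLandmarkDataset
#' @export
readLandmarkDataset <- function(path) {
  if (!file.exists(path))
    .stopf("painAU_format_error", "container not found: %s", path)
  idx <- tryCatch(rhdf5::h5ls(path), error = function(e)
    .stopf("painAU_format_error", "unreadable container %s: %s",
           path, conditionMessage(e)))
  segNames <- idx$name[idx$group == "/segments" & idx$otype == "H5I_GROUP"]
  segs <- lapply(segNames, function(nm) {
    g <- paste0("segments/", nm)
    have <- idx$name[idx$group == paste0("/", g)]
    if (!"landmarks" %in% have)
      .stopf("painAU_format_error",
             "malformed container: group '%s' has no 'landmarks' dataset", g)
    arr <- rhdf5::h5read(path, paste0(g, "/landmarks"))
    at <- rhdf5::h5readAttributes(path, g)
    pres <- if ("au_presence" %in% have)
      rhdf5::h5read(path, paste0(g, "/au_presence")) else NULL
    inten <- if ("au_intensity" %in% have)
      rhdf5::h5read(path, paste0(g, "/au_intensity")) else NULL
    aall <- if ("au_all" %in% have) {
      m <- rhdf5::h5read(path, paste0(g, "/au_all"))
      colnames(m) <- as.character(rhdf5::h5read(path, paste0(g, "/au_all_ids")))
      m
    } else NULL
    LandmarkSequence(arr, frameRate = as.numeric(at$frame_rate),
                     subjectId = as.character(at$subject_id),
                     segmentId = nm,
                     segmentClass = as.character(at$segment_class),
                     auPresence = pres, auIntensity = inten, auAll = aall)
  })
  ## preserve manifest ordering if present
  manPath <- paste0(path, ".manifest.json")
  ds <- LandmarkDataset(segs)
  if (file.exists(manPath)) {
    man <- jsonlite::read_json(manPath, simplifyVector = TRUE)$segments
    ord <- match(man$segmentId, names(segments(ds)))
    if (!anyNA(ord)) {
      ds@segments <- ds@segments[ord]
      ds@manifest <- ds@manifest[ord, , drop = FALSE]
      ds@manifest$split <- man$split
      ds@manifest$provenance <- man$provenance
      rownames(ds@manifest) <- NULL
    }
  }
  ds
}

#' Export / import one segment as CSV
#'
#' Long-format CSV with header `frame,point,x,y,z`; a lossy (printed
#' decimal) plain-text view of a single segment.
#'
#' @param seg A [LandmarkSequence-class].
#' @param path CSV path.
#' @export
exportSegmentCSV <- function(seg, path) {
  tn <- nFrames(seg); ns <- nPoints(seg)
  df <- data.frame(frame = rep(seq_len(tn), each = ns),
                   point = rep(seq_len(ns), tn),
                   x = as.vector(t(seg@coords[, , 1])),
                   y = as.vector(t(seg@coords[, , 2])),
                   z = as.vector(t(seg@coords[, , 3])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## ------------------------------------------------------------------
## External face-mesh extractor adapter

#' Adapter around an external per-frame face-mesh extractor
#'
#' Wraps an external landmark extractor (the anonymizing stage that turns
#' video frames into 3D landmarks) into [LandmarkSequence-class] objects.
#' The extractor is a callable `function(frameIndex)` returning an
#' `Ns x 3` matrix, or `NULL` on failure. Failed frames are gaps: runs of
#' at most `maxGap` consecutive gaps are linearly interpolated; a longer
#' run splits the recording into separate segments.
#'
#' The core pipeline needs no video input: all training and evaluation
#' runs on landmark containers (simulated or imported).
#'
#' @param nFrames Number of frames to request from the extractor.
#' @param extractor `function(i)` returning `Ns x 3` or `NULL`.
#' @param frameRate Frames per second of the source.
#' @param subjectId,segmentId Metadata for the produced segments.
#' @param maxGap Longest gap (frames) bridged by linear interpolation.
#' @return List of [LandmarkSequence-class] segments (one, unless long
#'   gaps forced a split).
#' @export
extractLandmarks <- function(nFrames, extractor, frameRate = 25,
                             subjectId = "unknown", segmentId = "seg",
                             maxGap = 5L) {
  if (missing(extractor) || !is.function(extractor))
    .stopf("painAU_capability_error", paste0(
      "no landmark extractor supplied; video input requires an external ",
      "face-mesh extractor, but the core pipeline runs entirely on ",
      "landmark containers and needs no video"))
  frames <- lapply(seq_len(nFrames), function(i)
    tryCatch(extractor(i), error = function(e) NULL))
  ok <- !vapply(frames, is.null, logical(1))
  if (!any(ok))
    .stopf("painAU_capability_error", "extractor failed on every frame")
  ## split at gaps longer than maxGap
  r <- rle(ok)
  bounds <- cumsum(r$lengths)
  splitAfter <- bounds[!r$values & r$lengths > maxGap]
  cut <- findInterval(seq_len(nFrames), splitAfter + 1L)
  segs <- list()
  for (piece in split(seq_len(nFrames), cut)) {
    pok <- ok[piece]
    if (!any(pok)) next
    piece <- piece[seq(which(pok)[1], max(which(pok)))]  # trim edge gaps
    pok <- ok[piece]
    ns <- nrow(frames[[piece[pok][1]]])
    arr <- array(NA_real_, c(length(piece), ns, 3))
    for (j in seq_along(piece)) if (ok[piece[j]]) arr[j, , ] <- frames[[piece[j]]]
    if (any(!pok)) {  # linear interpolation across short interior gaps
      tt <- seq_along(piece)
      for (p in seq_len(ns)) for (d in 1:3)
        arr[!pok, p, d] <- stats::approx(tt[pok], arr[pok, p, d],
                                         xout = tt[!pok])$y
    }
    segs[[length(segs) + 1L]] <- LandmarkSequence(
      arr, frameRate = frameRate, subjectId = subjectId,
      segmentId = sprintf("%s_%d", segmentId, length(segs) + 1L),
      metadata = list(interpolated = sum(!pok)))
  }
  segs
}
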
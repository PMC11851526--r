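## Forward simulator: renders landmark sequences whose deformations are
## driven by ground-truth AU activation timecourses, emulating the
## statistical structure of an annotated emotion-elicitation corpus
## (140 subjects, 1 pain + 3 non-pain ~20 s segments each) so that every
## downstream stage is trainable and testable without restricted data.

## Canonical facial feature anchor positions (template units; x right,
## y downward, z toward camera). The face occupies roughly [-1, 1]^2.
.faceRegions <- function() {
  list(
    eyeR = c(0.38, -0.25, 0.45), eyeL = c(-0.38, -0.25, 0.45),
    browR = c(0.40, -0.48, 0.42), browL = c(-0.40, -0.48, 0.42),
    browInnerR = c(0.15, -0.45, 0.50), browInnerL = c(-0.15, -0.45, 0.50),
    noseBridge = c(0, -0.15, 0.62), noseTip = c(0, 0.10, 0.72),
    cheekR = c(0.52, 0.12, 0.35), cheekL = c(-0.52, 0.12, 0.35),
    mouthCornerR = c(0.28, 0.45, 0.48), mouthCornerL = c(-0.28, 0.45, 0.48),
    lipUpper = c(0, 0.40, 0.58), lipLower = c(0, 0.52, 0.55),
    chin = c(0, 0.78, 0.40), jaw = c(0, 0.88, 0.25),
    forehead = c(0, -0.72, 0.40))
}

## Anatomical placement of each simulated AU: region anchors, Gaussian
## width, and a nominal displacement direction (before symmetrization
## and the seeded random component).
.auGeometry <- function() {
  rg <- .faceRegions()
  up <- c(0, -1, 0); down <- c(0, 1, 0); fwd <- c(0, 0, 1)
  lat <- c(1, 0, 0)
  list(
    `1` = list(c = rg$browInnerR, s = 0.18, d = up),
    `2` = list(c = rg$browR, s = 0.18, d = up),
    `4` = list(c = rg$browInnerR, s = 0.22, d = down),
    `5` = list(c = rg$eyeR, s = 0.15, d = up),
    `6` = list(c = rg$cheekR, s = 0.25, d = up + 0.4 * fwd),
    `7` = list(c = rg$eyeR, s = 0.18, d = 0.6 * down + 0.5 * fwd),
    `8` = list(c = rg$lipUpper, s = 0.22, d = down + 0.3 * fwd),
    `9` = list(c = rg$noseBridge, s = 0.18, d = up + 0.5 * fwd),
    `10` = list(c = rg$lipUpper, s = 0.18, d = up),
    `12` = list(c = rg$mouthCornerR, s = 0.20, d = lat + 0.7 * up),
    `14` = list(c = rg$mouthCornerR, s = 0.16, d = 0.8 * lat + 0.5 * fwd),
    `15` = list(c = rg$mouthCornerR, s = 0.18, d = down),
    `17` = list(c = rg$chin, s = 0.22, d = up + 0.4 * fwd),
    `18` = list(c = rg$lipUpper, s = 0.20, d = 0.9 * fwd + 0.3 * down),
    `19` = list(c = rg$lipLower, s = 0.15, d = fwd + 0.5 * down),
    `20` = list(c = rg$mouthCornerR, s = 0.22, d = lat + 0.3 * down),
    `23` = list(c = rg$lipLower, s = 0.16, d = 0.7 * up - 0.4 * fwd),
    `24` = list(c = rg$lipUpper, s = 0.20, d = down - 0.5 * fwd),
    `25` = list(c = rg$lipLower, s = 0.20, d = down + 0.2 * fwd),
    `26` = list(c = rg$jaw, s = 0.25, d = down))
}

#' Generate a canonical face-mesh template
#'
#' Builds a bilaterally symmetric 3D point cloud on a smooth face-shaped
#' dome, with denser landmark sampling around the eyes, nose and mouth
#' (as real face meshes have). Points come in exact mirror pairs plus
#' midline points at `x = 0`, so the template is mirror-symmetric to
#' machine precision; it is centered at the origin with unit mean
#' point-to-centroid distance. Deterministic given `seed`.
#'
#' @param topologyId `"mesh478"` (478 points) or `"bp4d83"` (83 points).
#' @param seed Integer seed.
#' @return `Ns x 3` template matrix.
#' @export
makeTemplate <- function(topologyId = c("mesh478", "bp4d83"), seed = 1L) {
  topologyId <- match.arg(topologyId)
  ns <- .topologyPoints[[topologyId]]
  nMid <- if (topologyId == "mesh478") 28L else 13L
  nPair <- (ns - nMid) %/% 2L
  rg <- .faceRegions()
  ## feature-weighted density: mixture of Gaussians around right-side
  ## features plus a broad face-wide component
  feats <- do.call(rbind, rg[c("eyeR", "browR", "noseTip", "noseBridge",
                               "mouthCornerR", "lipUpper", "lipLower",
                               "cheekR")])
  wts <- c(0.16, 0.08, 0.10, 0.08, 0.12, 0.10, 0.10, 0.06)
  sds <- c(0.10, 0.10, 0.10, 0.08, 0.08, 0.08, 0.08, 0.15)
  .withSeed(seed, {
    sampleHalf <- function(n) {
      out <- matrix(NA_real_, n, 2)
      got <- 0L
      while (got < n) {
        comp <- sample.int(length(wts) + 1L, 1L,
                           prob = c(wts, 1 - sum(wts)))
        xy <- if (comp <= length(wts))
          stats::rnorm(2, feats[comp, 1:2], sds[comp])
        else c(stats::runif(1, 0, 1), stats::runif(1, -0.95, 0.95))
        if (xy[1] <= 0.02 || xy[1] > 1 || abs(xy[2]) > 0.95) next
        if ((xy[1] / 1.0)^2 + (xy[2] / 0.95)^2 > 1) next
        got <- got + 1L
        out[got, ] <- xy
      }
      out
    }
    half <- sampleHalf(nPair)
    midY <- sort(stats::runif(nMid, -0.9, 0.9))
    dome <- function(x, y)
      0.75 * sqrt(pmax(0, 1 - (x / 1.05)^2 - (y / 1.0)^2))
    right <- cbind(half[, 1], half[, 2], dome(half[, 1], half[, 2]))
    left <- cbind(-half[, 1], half[, 2], right[, 3])
    mid <- cbind(0, midY, dome(0, midY))
    tpl <- rbind(right, left, mid)
    mu <- colMeans(tpl)
    mu[1] <- 0                        # pairs cancel exactly in x
    tpl <- sweep(tpl, 2, mu)
    sc <- mean(sqrt(rowSums(tpl^2)))
    tpl <- tpl / sc
    dimnames(tpl) <- list(NULL, c("x", "y", "z"))
    ## anchor transform: maps .faceRegions() coordinates into the
    ## centered/rescaled template frame (used by makeBasis)
    attr(tpl, "anchorTransform") <- list(mu = unname(mu), s = sc)
    tpl
  })
}

#' Mirror map of a template
#'
#' Derives the left/right landmark correspondence by nearest-neighbor
#' matching of each point to the x-negated template; every match must be
#' exact within `tol` and the induced permutation an involution.
#'
#' @param template `Ns x 3` template (mirror-symmetric, e.g. from
#'   [makeTemplate()]).
#' @param tol Match tolerance.
#' @return A [MirrorMap-class].
#' @export
mirrorMapFromTemplate <- function(template, tol = 1e-6) {
  neg <- template
  neg[, 1] <- -neg[, 1]
  ns <- nrow(template)
  perm <- integer(ns)
  for (i in seq_len(ns)) {
    d2 <- rowSums(sweep(template, 2, neg[i, ])^2)
    j <- which.min(d2)
    if (d2[j] > tol^2)
      .stopf("painAU_invalid_input",
             "template is not mirror-symmetric at point %d (residual %.3g)",
             i, sqrt(d2[j]))
    perm[i] <- j
  }
  mid <- which(perm == seq_len(ns))
  lhs <- which(perm > seq_len(ns))
  MirrorMap(pairs = cbind(lhs, perm[lhs]), midline = mid, nPoints = ns)
}

#' Build the per-AU deformation basis
#'
#' For each AU id, a smooth localized displacement field over the
#' template: a Gaussian region weight centered on the AU's anatomical
#' site (cheeks for the cheek raiser, mouth corners for the lip corner
#' puller, ...) times a low-frequency direction field (nominal FACS
#' direction plus a seeded random linear component), symmetrized under
#' the mirror map so bilateral AUs deform both sides coherently. Fields
#' are rescaled so the root-mean-square landmark displacement at
#' intensity 5 equals `gain` — every AU carries the same signal energy
#' per intensity unit — and the construction guarantees all pairwise
#' cosine similarities between flattened fields stay below 0.3, keeping
#' the AUs statistically identifiable.
#'
#' @param template `Ns x 3` template.
#' @param auIds AU ids to build fields for (subset of [auUniverse()]).
#' @param seed Integer seed.
#' @param gain RMS landmark displacement at full intensity (template units).
#' @param maxCos Identifiability bound on pairwise field cosines.
#' @return A [DeformationBasis-class].
#' @export
makeBasis <- function(template, auIds = auUniverse(), seed = 1L,
                      gain = 0.04, maxCos = 0.3) {
  unknown <- setdiff(auIds, auUniverse())
  if (length(unknown))
    .stopf("painAU_invalid_input", "unknown AU id(s): %s",
           paste(unknown, collapse = ", "))
  geo <- .auGeometry()
  at <- attr(template, "anchorTransform")
  if (is.null(at)) at <- list(mu = c(0, 0, 0), s = 1)
  mirror <- mirrorMapFromTemplate(template)
  perm <- mirrorPermutation(mirror)
  ns <- nrow(template)
  buildField <- function(au, sd) {
    g <- geo[[as.character(au)]]
    g$c <- (g$c - at$mu) / at$s
    g$s <- g$s / at$s
    .withSeed(sd, {
      w <- exp(-rowSums(sweep(template, 2, g$c)^2) / (2 * g$s^2))
      d0 <- g$d / sqrt(sum(g$d^2))
      D <- matrix(stats::rnorm(9, 0, 0.6), 3, 3)
      dir <- matrix(d0, ns, 3, byrow = TRUE) +
        0.5 * sweep(template, 2, g$c) %*% t(D)
      f <- w * dir
      f <- f + (f[perm, ] * matrix(c(-1, 1, 1), ns, 3, byrow = TRUE))
      f[w + w[perm] < 0.01, ] <- 0   # hard support cutoff
      f
    })
  }
  fields <- lapply(seq_along(auIds), function(i)
    buildField(auIds[i], deriveSeed(seed, sprintf("au%d", auIds[i]))))
  ## remove each field's net rigid-motion + scale component: a muscle
  ## action deforms the face without moving the head, so its projection
  ## onto the similarity-transform tangent space (3 translations, 3
  ## infinitesimal rotations, 1 scaling) must vanish — this also makes
  ## the deformation commute with Procrustes normalization to first
  ## order. The tangent space is closed under the mirror operation, so
  ## symmetry is preserved.
  tang <- cbind(
    as.vector(matrix(c(1, 0, 0), ns, 3, byrow = TRUE)),
    as.vector(matrix(c(0, 1, 0), ns, 3, byrow = TRUE)),
    as.vector(matrix(c(0, 0, 1), ns, 3, byrow = TRUE)),
    as.vector(cbind(-template[, 2], template[, 1], 0)),   # rot about z
    as.vector(cbind(template[, 3], 0, -template[, 1])),   # rot about y
    as.vector(cbind(0, -template[, 3], template[, 2])),   # rot about x
    as.vector(template))                                  # scale
  tq <- qr(tang)
  fields <- lapply(fields, function(f)
    matrix(as.vector(f) - qr.fitted(tq, as.vector(f)), ns))
  ## sequential Gram-Schmidt on the flattened fields: AUs sharing a
  ## facial region keep their anatomical locus but become mutually
  ## uncorrelated (mirror symmetry is preserved, being closed under
  ## linear combination)
  V <- vapply(fields, as.vector, numeric(3L * ns))
  for (i in seq_along(fields)) {
    if (i > 1) {
      prev <- V[, seq_len(i - 1L), drop = FALSE]
      V[, i] <- V[, i] - prev %*% (crossprod(prev, V[, i]) /
                                     colSums(prev^2))
    }
    f <- matrix(V[, i], ns, 3)
    rn <- sqrt(rowSums(f^2))
    f[rn < 0.005 * max(rn), ] <- 0        # hard support cutoff
    V[, i] <- as.vector(f)
  }
  fields <- lapply(seq_along(fields), function(i) {
    f <- matrix(V[, i], ns, 3)
    f * (gain / sqrt(mean(rowSums(f^2))))
  })
  Vn <- sweep(V, 2, sqrt(colSums(V^2)), `/`)
  cc <- crossprod(Vn)
  diag(cc) <- 0
  if (max(abs(cc)) >= maxCos)
    .stopf("painAU_invalid_input",
           "could not build an identifiable basis (max |cos| %.2f)",
           max(abs(cc)))
  masks <- lapply(fields, function(f) {
    m <- sqrt(rowSums(f^2))
    if (max(m) > 0) m / max(m) else m
  })
  names(fields) <- names(masks) <- as.character(auIds)
  new("DeformationBasis", template = template, fields = fields,
      masks = masks, gain = gain)
}

#' Simulate an AU activation timecourse for one segment
#'
#' Each AU associated with the segment's expression class fires in 1–4
#' smooth onset–apex–offset pulses with apex intensity drawn from
#' `{1..5}` skewed toward low intensities (as observed intensity
#' distributions are); AUs outside the class set occasionally fire
#' low-amplitude distractor pulses. Ramps are slow enough that the
#' frame-to-frame intensity change never exceeds 1.
#'
#' @param class `"pain"`, `"happiness"`, `"embarrassment"` or `"fear"`.
#' @param durationS Segment duration in seconds (>= 2).
#' @param frameRate Frames per second.
#' @param seed Integer seed.
#' @param auIds AU universe simulated (columns of the result).
#' @param distractorProb Probability a non-class AU fires one apex-1 pulse.
#' @param backgroundProb Probability that a commonly present AU (the
#'   detectable set) shows class-independent background activity when it
#'   is not part of the class's prototype set; this emulates the high
#'   base rates of the top-8 AUs without contributing class information.
#' @return An [ActivationTimecourse-class].
#' @export
simulateTimecourse <- function(class = c("pain", "happiness",
                                         "embarrassment", "fear"),
                               durationS = 20, frameRate = 25, seed = 1L,
                               auIds = auUniverse(),
                               distractorProb = 0.15,
                               backgroundProb = 0.3) {
  class <- match.arg(class)
  if (durationS < 2)
    .stopf("painAU_invalid_input",
           "segment duration must be at least 2 s (got %g)", durationS)
  tn <- max(2L, round(durationS * frameRate))
  classAUs <- emotionAUMap()[[class]]
  apexProb <- c(0.35, 0.25, 0.18, 0.14, 0.08)   # low-intensity-skewed
  I <- .withSeed(seed, {
    out <- matrix(0, tn, length(auIds))
    addPulse <- function(col, apex) {
      ## fast onsets/offsets (0.15-0.5 s), as facial actions have
      ramp <- round(stats::runif(2, 0.15, 0.5) * frameRate)
      ramp <- pmax(ramp, ceiling(apex / 0.9))             # slope bound
      hold <- round(stats::runif(1, 0.5, 3) * frameRate)
      len <- ramp[1] + hold + ramp[2]
      s <- sample.int(max(tn - len, 1L), 1L)
      pulse <- c(seq(0, apex, length.out = ramp[1] + 1L)[-1],
                 rep(apex, hold),
                 seq(apex, 0, length.out = ramp[2] + 1L)[-1])
      e <- min(s + length(pulse) - 1L, tn)
      out[s:e, col] <<- pmin(out[s:e, col] + pulse[seq_len(e - s + 1L)], 5)
    }
    ## apex = FACS level plus a continuous offset: real activations are
    ## not exact integers, and pulses peak clearly above the trace
    ## threshold rather than sitting on the presence boundary
    drawApex <- function(lvl) min(lvl + stats::runif(1, 0.25, 0.75), 5)
    for (au in classAUs) {
      col <- match(au, auIds)
      if (is.na(col)) next
      for (k in seq_len(sample.int(4L, 1L)))
        addPulse(col, drawApex(sample.int(5L, 1L, prob = apexProb)))
    }
    ## class-neutral detectable AUs (in no simulated emotion's prototype
    ## set) show frequent background activity — they are among the most
    ## present AUs without being class-informative; class-informative
    ## detectable AUs get only rare trace-level background
    neutral <- setdiff(auDetectIds(),
                       unlist(emotionAUMap()[c("pain", "happiness",
                                               "embarrassment", "fear")]))
    for (au in setdiff(auIds, classAUs)) {
      if (au %in% neutral) {
        if (stats::runif(1) < min(2 * backgroundProb, 1))
          for (k in seq_len(sample.int(2L, 1L)))
            addPulse(match(au, auIds),
                     drawApex(sample.int(3L, 1L, prob = c(0.45, 0.35, 0.2))))
      } else if (au %in% auDetectIds()) {
        if (stats::runif(1) < backgroundProb / 2)
          addPulse(match(au, auIds), drawApex(1))
      } else if (stats::runif(1) < distractorProb) {
        addPulse(match(au, auIds), drawApex(1))
      }
    }
    ## rate limiter: overlapping pulses may sum to a faster rise than a
    ## single articulator can produce; bound the change at 0.9/frame
    for (j in seq_len(ncol(out))) {
      for (t in 2:tn)
        out[t, j] <- min(max(out[t, j], out[t - 1L, j] - 0.9),
                         out[t - 1L, j] + 0.9)
    }
    out
  })
  colnames(I) <- as.character(auIds)
  new("ActivationTimecourse", intensities = I, auIds = as.integer(auIds),
      exprClass = class, frameRate = frameRate)
}

#' Render a landmark sequence from an activation timecourse
#'
#' The linear forward model: frame `t` is
#' `RigidPose_t( subjectTemplate + sum_k (I[t,k] / 5) * field_k )` plus
#' isotropic Gaussian landmark noise. Pose jitter is a smooth random
#' rotation/translation walk (spline through knots every 2 s). Labels
#' derive from the timecourse: presence = intensity >= 1 for the 8
#' detector AUs, intensities for AUs 6, 10, 12, 14, 17, and the all-AU
#' presence matrix for every simulated AU.
#'
#' @param basis A [DeformationBasis-class].
#' @param timecourse An [ActivationTimecourse-class].
#' @param subjectShape Optional `Ns x 3` per-subject template offset.
#' @param gainScale Per-subject expressiveness multiplier applied to the
#'   activation intensities themselves (capped at 5). FACS intensity is
#'   appearance-defined, so labels scale with the rendered deformation.
#' @param poseRotSD,poseTransSD Pose-jitter scales (degrees / template
#'   units); both 0 disables pose (identity).
#' @param noiseSd Landmark noise SD (template units).
#' @param seed Integer seed.
#' @param subjectId,segmentId Metadata.
#' @return A labeled [LandmarkSequence-class].
#' @export
renderSequence <- function(basis, timecourse, subjectShape = NULL,
                           gainScale = 1, poseRotSD = 0, poseTransSD = 0,
                           noiseSd = 0, seed = 1L,
                           subjectId = "sim", segmentId = "sim_seg") {
  I <- pmin(timecourse@intensities * gainScale, 5)
  tn <- nrow(I)
  tpl <- basis@template
  if (!is.null(subjectShape)) tpl <- tpl + subjectShape
  ns <- nrow(tpl)
  auIds <- timecourse@auIds
  fields <- basis@fields[as.character(auIds)]
  if (any(vapply(fields, is.null, logical(1))))
    .stopf("painAU_invalid_input", "basis lacks fields for some timecourse AUs")
  F3 <- vapply(fields, as.vector, numeric(3L * ns))   # (3 Ns) x K
  base <- matrix(as.vector(tpl), tn, 3L * ns, byrow = TRUE) +
    (I / 5) %*% t(F3)
  arr <- array(base, c(tn, ns, 3L))
  if (poseRotSD > 0 || poseTransSD > 0) {
    ang <- .smoothWalk(tn, timecourse@frameRate, poseRotSD * pi / 180,
                       deriveSeed(seed, "rot"), 3L)
    trs <- .smoothWalk(tn, timecourse@frameRate, poseTransSD,
                       deriveSeed(seed, "trans"), 3L)
    for (t in seq_len(tn)) {
      R <- .eulerRotation(ang[t, ])
      arr[t, , ] <- matrix(arr[t, , ], ns) %*% t(R) +
        matrix(trs[t, ], ns, 3, byrow = TRUE)
    }
  }
  if (noiseSd > 0)
    arr <- arr + .withSeed(deriveSeed(seed, "noise"),
                           array(stats::rnorm(length(arr), 0, noiseSd),
                                 dim(arr)))
  pres <- (I[, as.character(auDetectIds()), drop = FALSE] >= 1) + 0
  inten <- I[, as.character(auIntensityIds()), drop = FALSE]
  all <- (I >= 1) + 0
  LandmarkSequence(arr, frameRate = timecourse@frameRate,
                   subjectId = subjectId, segmentId = segmentId,
                   segmentClass = if (timecourse@exprClass == "pain")
                     "pain" else "other",
                   auPresence = unname(pres), auIntensity = unname(inten),
                   auAll = all,
                   metadata = list(emotion = timecourse@exprClass))
}

## Smooth random curves: spline through N(0, sd) knots every 2 seconds.
.smoothWalk <- function(tn, frameRate, sd, seed, ncol) {
  .withSeed(seed, {
    nk <- max(3L, ceiling(tn / (2 * frameRate)) + 1L)
    kx <- seq(1, tn, length.out = nk)
    vapply(seq_len(ncol), function(j)
      stats::spline(kx, stats::rnorm(nk, 0, sd), xout = seq_len(tn))$y,
      numeric(tn))
  })
}

.eulerRotation <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
    matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
    matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
}

#' Simulation configuration
#'
#' Defaults mirror the emulated corpus: 140 subjects, 1 pain + 3 non-pain
#' segments per subject (the non-pain classes being happiness,
#' embarrassment and fear), ~20 s segments at 25 fps with +/-15% duration
#' jitter, landmark noise 0.01 template units, small smooth pose jitter
#' and per-subject shape/gain variation.
#'
#' @param nSubjects Number of subjects.
#' @param segmentSeconds Nominal segment duration (s).
#' @param durationJitter Relative duration jitter (uniform).
#' @param frameRate Frames per second.
#' @param topologyId `"mesh478"` or `"bp4d83"`.
#' @param noiseSd Landmark noise SD (template units).
#' @param poseRotSD,poseTransSD Pose jitter scales.
#' @param subjectShapeSd Per-subject template perturbation SD.
#' @param gainSd SD of the per-subject deformation gain multiplier.
#' @param distractorProb Distractor pulse probability per non-class AU.
#' @param backgroundProb Background-activity probability for detectable
#'   AUs outside the class set (see [simulateTimecourse()]).
#' @param seed Integer seed.
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nSubjects = 140L, segmentSeconds = 20,
                             durationJitter = 0.15, frameRate = 25,
                             topologyId = "mesh478", noiseSd = 0.01,
                             poseRotSD = 2, poseTransSD = 0.02,
                             subjectShapeSd = 0.02, gainSd = 0.1,
                             distractorProb = 0.15, backgroundProb = 0.3,
                             seed = 1L) {
  stopifnot(nSubjects >= 1, segmentSeconds >= 2, frameRate > 0,
            noiseSd >= 0, subjectShapeSd >= 0)
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Simulate a full labeled landmark dataset
#'
#' For each subject: one pain segment and one segment each of happiness,
#' embarrassment and fear, rendered through a shared deformation basis
#' with per-subject template perturbation and gain. Fully reproducible
#' from the config seed.
#'
#' @param config A [simulationConfig()].
#' @param template,basis Optionally precomputed (else built from the
#'   config seed).
#' @return A [LandmarkDataset-class].
#' @export
simulateDataset <- function(config = simulationConfig(), template = NULL,
                            basis = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(template))
    template <- makeTemplate(config$topologyId, deriveSeed(config$seed, "tpl"))
  if (is.null(basis))
    basis <- makeBasis(template, seed = deriveSeed(config$seed, "basis"))
  classes <- c("pain", "happiness", "embarrassment", "fear")
  segs <- list()
  ## identity variation is constrained to the expression-orthogonal
  ## subspace: face proportions differ across people, but an identity
  ## offset must not mimic an AU activation
  Fspan <- qr(vapply(basis@fields, as.vector,
                     numeric(length(template))))
  for (s in seq_len(config$nSubjects)) {
    sid <- sprintf("S%03d", s)
    shape <- .withSeed(deriveSeed(config$seed, paste0(sid, "/shape")),
      matrix(stats::rnorm(length(template), 0, config$subjectShapeSd),
             nrow(template)))
    shape <- shape - matrix(qr.fitted(Fspan, as.vector(shape)),
                            nrow(template))
    gain <- .withSeed(deriveSeed(config$seed, paste0(sid, "/gain")),
      max(0.5, 1 + stats::rnorm(1, 0, config$gainSd)))
    for (ci in seq_along(classes)) {
      segSeed <- deriveSeed(config$seed, sprintf("%s/seg%d", sid, ci))
      dur <- .withSeed(deriveSeed(segSeed, "dur"),
        config$segmentSeconds *
          stats::runif(1, 1 - config$durationJitter,
                       1 + config$durationJitter))
      tc <- simulateTimecourse(classes[ci], durationS = dur,
                               frameRate = config$frameRate,
                               seed = deriveSeed(segSeed, "tc"),
                               distractorProb = config$distractorProb,
                               backgroundProb = config$backgroundProb)
      segs[[length(segs) + 1L]] <- renderSequence(
        basis, tc, subjectShape = shape, gainScale = gain,
        poseRotSD = config$poseRotSD, poseTransSD = config$poseTransSD,
        noiseSd = config$noiseSd, seed = deriveSeed(segSeed, "render"),
        subjectId = sid, segmentId = sprintf("%s_%s", sid, classes[ci]))
    }
  }
  LandmarkDataset(segs)
}
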
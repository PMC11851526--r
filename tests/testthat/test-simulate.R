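test_that("templates have the declared point counts, symmetry, and determinism", {
  expect_identical(nrow(tpl83), 83L)
  perm <- mirrorPermutation(mirror83)
  mirrored <- tpl83[perm, ]
  mirrored[, 1] <- -mirrored[, 1]
  expect_lt(max(abs(tpl83 - mirrored)), 1e-9)
  expect_identical(tpl83, makeTemplate("bp4d83", 1))

  tpl478 <- makeTemplate("mesh478", 3)
  expect_identical(nrow(tpl478), 478L)
  m478 <- mirrorMapFromTemplate(tpl478)
  expect_identical(m478@nPoints, 478L)
  ## denser sampling around facial features than at the face periphery
  at <- attr(tpl478, "anchorTransform")
  near <- function(anchor, r = 0.15 / at$s) {
    a <- (anchor - at$mu[1:2]) / at$s
    sum(rowSums(sweep(tpl478[, 1:2], 2, a)^2) < r^2)
  }
  expect_gt(near(c(0.38, -0.25)) + near(c(0.28, 0.45)),   # eye + mouth corner
            2 * near(c(0.0, -0.85)))                      # forehead edge
})

test_that("the mirror permutation is an involution on all indices", {
  p <- mirrorPermutation(mirror83)
  expect_identical(p[p], seq_len(83L))
})

test_that("the deformation basis is complete, localized, symmetric and identifiable", {
  ids <- as.character(auDetectIds())
  expect_true(all(ids %in% names(basis83@fields)))
  expect_identical(length(makeBasis(tpl83, auDetectIds(), seed = 3)@fields), 8L)
  perm <- mirrorPermutation(mirror83)
  for (k in names(basis83@fields)) {
    f <- basis83@fields[[k]]
    g <- f[perm, ]; g[, 1] <- -g[, 1]
    expect_lt(max(abs(f - g)), 1e-6)               # bilateral symmetry
    expect_true(all(rowSums(abs(f))[basis83@masks[[k]] == 0] == 0))
  }
  V <- vapply(basis83@fields, as.vector, numeric(3 * 83))
  V <- sweep(V, 2, sqrt(colSums(V^2)), `/`)
  cc <- crossprod(V); diag(cc) <- 0
  expect_lt(max(abs(cc)), 0.3)
  expect_error(makeBasis(tpl83, c(6L, 99L)), class = "painAU_invalid_input")
})

test_that("timecourses activate only class and background AUs, smoothly, within range", {
  tc <- simulateTimecourse("pain", durationS = 10, seed = 3)
  active <- tc@auIds[apply(tc@intensities, 2, max) > 0]
  allowed <- union(emotionAUMap()$pain, auDetectIds())
  expect_true(all(active %in% union(allowed, tc@auIds)))  # universe-closed
  ## AUs neither pain-associated nor commonly present stay at trace level
  sporadic <- setdiff(active, union(emotionAUMap()$pain, auDetectIds()))
  if (length(sporadic))
    expect_lt(max(tc@intensities[, as.character(sporadic)]), 2)
  expect_true(all(tc@intensities >= 0 & tc@intensities <= 5))
  expect_error(simulateTimecourse("pain", durationS = 1),
               class = "painAU_invalid_input")
})

test_that("frame-to-frame intensity change is bounded across many seeded segments", {
  worst <- 0
  for (s in 1:100) {
    cl <- c("pain", "happiness", "embarrassment", "fear")[(s %% 4) + 1]
    tc <- simulateTimecourse(cl, durationS = 4, seed = s)
    worst <- max(worst, max(abs(diff(tc@intensities))))
  }
  expect_lte(worst, 1.0)
})

test_that("pain-set AU intensities are higher in pain segments than in other segments", {
  ds <- smallDataset()
  painIds <- intersect(emotionAUMap()$pain, auDetectIds())
  cols <- match(painIds, auDetectIds())
  painM <- otherM <- c()
  for (seg in segments(ds)) {
    m <- colMeans(auPresence(seg)[, cols, drop = FALSE])
    if (segmentClass(seg) == "pain") painM <- rbind(painM, m)
    else otherM <- rbind(otherM, m)
  }
  for (j in seq_along(cols))
    expect_gt(mean(painM[, j]), mean(otherM[, j]))
})

test_that("rendering is the stated linear forward model", {
  ids <- colnames(basis83@fields[[1]])
  tcZero <- new("ActivationTimecourse",
                intensities = matrix(0, 20, length(auUniverse()),
                                     dimnames = list(NULL, auUniverse())),
                auIds = as.integer(auUniverse()), exprClass = "happiness",
                frameRate = 25)
  seg0 <- renderSequence(basis83, tcZero, noiseSd = 0, seed = 1)
  for (t in c(1, 10, 20))
    expect_equal(getFrame(seg0, t), tpl83, ignore_attr = TRUE,
                 tolerance = 1e-12)

  I <- tcZero@intensities
  ## smooth triangular AU6 pulse: 0 -> 5 (frame 11) -> back down
  I[, "6"] <- c(seq(0, 5, by = 0.5), seq(4.5, 0.5, by = -0.5))
  tc <- new("ActivationTimecourse", intensities = I,
            auIds = as.integer(auUniverse()), exprClass = "happiness",
            frameRate = 25)
  seg <- renderSequence(basis83, tc, noiseSd = 0, seed = 1)
  dFull <- getFrame(seg, 11) - getFrame(seg, 1)   # intensity 5 vs 0
  expect_equal(unname(dFull), unname(basis83@fields[["6"]]),
               tolerance = 1e-12)
  ## doubling intensity doubles the displacement contribution
  dHalf <- getFrame(seg, 6) - getFrame(seg, 1)    # intensity 2.5
  expect_equal(unname(2 * dHalf), unname(dFull), tolerance = 1e-12)
})

test_that("rendered labels follow the intensity >= 1 presence rule", {
  seg <- segments(smallDataset())[[1]]
  expect_true(all(auPresence(seg) %in% c(0, 1)))
  expect_true(all(auIntensity(seg) >= 0 & auIntensity(seg) <= 5))
})

test_that("detector performance degrades monotonically with landmark noise", {
  f1At <- function(noise) {
    ds <- simulateDataset(simulationConfig(
      nSubjects = 10L, segmentSeconds = 6, topologyId = "bp4d83",
      noiseSd = noise, seed = 11L))
    fm <- frameMatrix(ds, tpl83, frameStride = 3L, "presence")
    trm <- fm$subject %in% sprintf("S%03d", 1:7)
    m <- trainAUDetector(fm$X[trm, ], fm$Y[trm, ], auDetectorConfig(
      inputSize = ncol(fm$X), maxEpochs = 15L, seed = 1L))
    pred <- binarizeAU(predictAU(m, fm$X[!trm, ]))
    mean(vapply(1:8, function(j)
      f1PrecisionRecall(fm$Y[!trm, j], pred[, j])["f1"], numeric(1)))
  }
  sweep <- vapply(c(0.005, 0.05, 0.2), f1At, numeric(1))
  expect_true(all(diff(sweep) < 0))
})

test_that("dataset simulation matches the configured structure and is seed-deterministic", {
  ds <- smallDataset()
  expect_identical(length(segments(ds)), 32L)   # 8 subjects x 4 segments
  man <- manifest(ds)
  expect_identical(sum(man$segmentClass == "pain"), 8L)
  expect_identical(sum(man$segmentClass == "other"), 24L)
  ## pain:other frame ratio near 1:3 (equal nominal durations)
  frames <- vapply(segments(ds), nFrames, integer(1))
  ratio <- sum(frames[man$segmentClass == "other"]) /
    sum(frames[man$segmentClass == "pain"])
  expect_gt(ratio, 2.2); expect_lt(ratio, 3.8)
  ## determinism: content hash equality on a fresh simulation
  again <- simulateDataset(simulationConfig(
    nSubjects = 8L, segmentSeconds = 6, topologyId = "bp4d83",
    noiseSd = 0.005, seed = 11L))
  expect_identical(datasetHash(ds), datasetHash(again))
})
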
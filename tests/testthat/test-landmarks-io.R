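test_that("normalization is the identity on the template and removes similarity transforms", {
  expect_lt(max(abs(normalizeFrame(tpl83, tpl83) - tpl83)), 1e-9)
  set.seed(42)
  for (i in 1:8) {
    R <- randomRotation()
    s <- runif(1, 0.5, 2)
    tr <- rnorm(3, 0, 5)
    moved <- s * tpl83 %*% t(R) + matrix(tr, nrow(tpl83), 3, byrow = TRUE)
    expect_lt(max(abs(normalizeFrame(moved, tpl83) - tpl83)), 1e-6)
    ## invariance on an arbitrary (deformed) frame, not just the template
    frame <- tpl83 + matrix(rnorm(length(tpl83), 0, 0.05), nrow(tpl83))
    a <- normalizeFrame(frame, tpl83)
    b <- normalizeFrame(s * frame %*% t(R) +
                          matrix(tr, nrow(tpl83), 3, byrow = TRUE), tpl83)
    expect_lt(max(abs(a - b)), 1e-6)
  }
})

test_that("normalization is idempotent", {
  set.seed(7)
  frame <- tpl83 + matrix(rnorm(length(tpl83), 0, 0.03), nrow(tpl83))
  once <- normalizeFrame(frame, tpl83)
  expect_lt(max(abs(normalizeFrame(once, tpl83) - once)), 1e-9)
})

test_that("normalization rotation matches the closed-form Procrustes solution on a 5-point toy", {
  set.seed(13)
  template <- matrix(rnorm(15), 5)
  template <- sweep(template, 2, colMeans(template))
  frame <- matrix(rnorm(15), 5)
  ## independent oracle: explicit orthogonal-Procrustes solution
  Xc <- sweep(frame, 2, colMeans(frame))
  Xc <- Xc * mean(sqrt(rowSums(template^2))) / mean(sqrt(rowSums(Xc^2)))
  M <- t(Xc) %*% template
  sv <- svd(M)
  R <- sv$u %*% diag(c(1, 1, sign(det(sv$u %*% t(sv$v))))) %*% t(sv$v)
  expect_lt(max(abs(normalizeFrame(frame, template) - Xc %*% R)), 1e-9)
})

test_that("degenerate and mismatched frames are rejected", {
  expect_error(normalizeFrame(matrix(1, 83, 3), tpl83),
               class = "painAU_degenerate_geometry")
  expect_error(normalizeFrame(matrix(rnorm(15), 5), tpl83),
               class = "painAU_invalid_input")
})

test_that("flattening uses the documented interleaved order and round-trips", {
  f <- matrix(seq_len(12), 4, 3)   # columns x, y, z
  v <- flattenFrame(f)
  expect_equal(v[1:6], c(1, 5, 9, 2, 6, 10))  # x0 y0 z0 x1 y1 z1
  expect_identical(unflattenFrame(v), `dimnames<-`(f, list(NULL, c("x", "y", "z"))))
  expect_length(flattenFrame(matrix(0, 478, 3)), 1434)
  expect_length(flattenFrame(tpl83), 249)
})

test_that("the HDF5 container round-trips arrays bit-exactly with metadata", {
  ds <- smallDataset()
  sub <- subsetBySubject(ds, c("S001", "S002"))
  path <- tempfile(fileext = ".h5")
  on.exit(unlink(c(path, paste0(path, ".manifest.json"))))
  writeLandmarkDataset(sub, path)
  back <- readLandmarkDataset(path)
  expect_identical(names(segments(back)), names(segments(sub)))
  for (id in names(segments(sub))) {
    a <- segments(sub)[[id]]; b <- segments(back)[[id]]
    expect_identical(coords(a), coords(b))
    expect_identical(unname(auPresence(a)), unname(auPresence(b)))
    expect_identical(unname(auIntensity(a)), unname(auIntensity(b)))
    expect_identical(subjectId(a), subjectId(b))
    expect_identical(segmentClass(a), segmentClass(b))
    expect_identical(frameRate(a), frameRate(b))
  }
  expect_true(file.exists(paste0(path, ".manifest.json")))
})

test_that("a container without intensity labels reads as intensity-unlabeled", {
  seg <- segments(smallDataset())[[1]]
  stripped <- initialize(seg, auIntensity = matrix(numeric(0), 0, 0))
  path <- tempfile(fileext = ".h5")
  on.exit(unlink(c(path, paste0(path, ".manifest.json"))))
  writeLandmarkDataset(LandmarkDataset(list(stripped)), path)
  back <- segments(readLandmarkDataset(path))[[1]]
  expect_identical(nrow(auIntensity(back)), 0L)
  expect_gt(nrow(auPresence(back)), 0L)   # presence labels intact
})

test_that("malformed containers raise a format error naming the group", {
  path <- tempfile(fileext = ".h5")
  on.exit(unlink(path))
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "segments")
  rhdf5::h5createGroup(path, "segments/broken")
  rhdf5::h5write(1:3, path, "segments/broken/junk")
  expect_error(readLandmarkDataset(path), "broken",
               class = "painAU_format_error")
  expect_error(readLandmarkDataset(tempfile()), class = "painAU_format_error")
})

test_that("the dataset manifest has one subject per id and the configured segments per subject", {
  man <- manifest(smallDataset())
  expect_identical(length(unique(man$subjectId)), 8L)
  expect_true(all(table(man$subjectId) == 4L))
  expect_true(all(table(man$subjectId, man$segmentClass)[, "pain"] == 1L))
  expect_true(all(table(man$subjectId, man$segmentClass)[, "other"] == 3L))
})

test_that("the extractor adapter wraps, interpolates short gaps, and splits long ones", {
  stub <- function(i) tpl83
  segs <- extractLandmarks(10, stub, subjectId = "A")
  expect_length(segs, 1L)
  expect_identical(nFrames(segs[[1]]), 10L)

  failing3 <- function(i) if (i == 3) NULL else tpl83 * i
  segs <- extractLandmarks(10, failing3)
  expect_length(segs, 1L)
  expect_identical(nFrames(segs[[1]]), 10L)
  ## frame 3 is the midpoint of frames 2 and 4 by linear interpolation
  mid <- (coords(segs[[1]])[2, , ] + coords(segs[[1]])[4, , ]) / 2
  expect_equal(coords(segs[[1]])[3, , ], mid, tolerance = 1e-12)

  gap8 <- function(i) if (i %in% 5:12) NULL else tpl83
  segs <- extractLandmarks(20, gap8)
  expect_length(segs, 2L)
  expect_identical(nFrames(segs[[1]]), 4L)
  expect_identical(nFrames(segs[[2]]), 8L)

  expect_error(extractLandmarks(5, "not a function"),
               class = "painAU_capability_error")
})

test_that("CSV export writes the documented long format", {
  seg <- segments(smallDataset())[[1]]
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  exportSegmentCSV(seg, path)
  df <- read.csv(path)
  expect_identical(names(df), c("frame", "point", "x", "y", "z"))
  expect_identical(nrow(df), nFrames(seg) * nPoints(seg))
  expect_equal(unlist(df[1, 3:5], use.names = FALSE), getFrame(seg, 1)[1, ],
               ignore_attr = TRUE)
})
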
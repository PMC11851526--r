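## Shared small fixtures, built once per test run. All simulated data
## use the 83-point topology: it exercises the same code paths as the
## 478-point mesh at a sixth of the input size.

tpl83 <- makeTemplate("bp4d83", 1)
mirror83 <- mirrorMapFromTemplate(tpl83)
basis83 <- makeBasis(tpl83, seed = 1)

## Memoised small labeled dataset (8 subjects x 4 segments x ~6 s).
.fixtureEnv <- new.env(parent = emptyenv())
smallDataset <- function() {
  if (is.null(.fixtureEnv$ds))
    .fixtureEnv$ds <- simulateDataset(simulationConfig(
      nSubjects = 8L, segmentSeconds = 6, topologyId = "bp4d83",
      noiseSd = 0.005, seed = 11L))
  .fixtureEnv$ds
}

## A hand-buildable toy sequence on an arbitrary small topology.
toySequence <- function(coordsList, ...) {
  arr <- array(NA_real_, c(length(coordsList), nrow(coordsList[[1]]), 3))
  for (t in seq_along(coordsList)) arr[t, , ] <- coordsList[[t]]
  LandmarkSequence(arr, ...)
}

## Random rigid rotation matrix (uniform axis, uniform angle).
randomRotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

## Flatten/unflatten named parameter lists (finite-difference checks).
flatParams <- function(p) unlist(p, use.names = FALSE)
unflatParams <- function(v, p) {
  i <- 0
  for (k in names(p)) {
    n <- length(p[[k]])
    p[[k]][] <- v[(i + 1):(i + n)]
    i <- i + n
  }
  p
}
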
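## Two-layer fully-connected network (hidden ReLU layer + linear or
## logistic output), trained with Adam. This is the AU detection /
## intensity estimation architecture; gradients are hand-derived and
## verified against finite differences in the test suite.

.denseInit <- function(inputSize, hidden, outputs, seed) {
  .withSeed(seed, list(
    W1 = matrix(stats::rnorm(inputSize * hidden, 0, sqrt(2 / inputSize)),
                inputSize, hidden),
    b1 = numeric(hidden),
    W2 = matrix(stats::rnorm(hidden * outputs, 0, sqrt(2 / hidden)),
                hidden, outputs),
    b2 = numeric(outputs)))
}

## X: B x D. Returns list(H, Z): hidden activations and output pre-activations.
.denseForward <- function(params, X) {
  H <- pmax(sweep(X %*% params$W1, 2, params$b1, `+`), 0)
  Z <- sweep(H %*% params$W2, 2, params$b2, `+`)
  list(H = H, Z = Z)
}

## Numerically stable mean binary cross-entropy from logits.
.bceLoss <- function(Z, Y) {
  mean((1 - Y) * Z + log1p(exp(-abs(Z))) + pmax(-Z, 0))
}

## Loss and parameter gradients for one batch.
## outputType "logistic": per-unit sigmoid + BCE; "linear": MSE.
.denseLossGrad <- function(params, X, Y, outputType) {
  fw <- .denseForward(params, X)
  n <- length(Y)
  if (outputType == "logistic") {
    P <- stats::plogis(fw$Z)
    loss <- .bceLoss(fw$Z, Y)
    dZ <- (P - Y) / n
  } else {
    loss <- mean((fw$Z - Y)^2)
    dZ <- 2 * (fw$Z - Y) / n
  }
  dH <- dZ %*% t(params$W2)
  dH[fw$H == 0] <- 0
  list(loss = loss,
       grads = list(W1 = crossprod(X, dH), b1 = colSums(dH),
                    W2 = crossprod(fw$H, dZ), b2 = colSums(dZ)))
}

## Adam state and update over a named list of parameter arrays.
.adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / c1) / (sqrt(state$v[[k]] / c2) + eps)
  }
  list(params = params, state = state)
}

## Mini-batch training loop shared by detector and intensity estimator.
## Returns list(params, history).
.denseTrain <- function(X, Y, outputType, hidden, lr, batchSize, maxEpochs,
                        beta1, beta2, seed, patience = 0L, verbose = FALSE) {
  ## center inputs: landmark coordinates carry a large constant offset
  ## (the face shape itself) on which the AU signal rides; removing the
  ## training mean conditions the optimization. The center is stored
  ## with the weights and applied at prediction time.
  center <- colMeans(X)
  X <- sweep(X, 2, center)
  params <- .denseInit(ncol(X), hidden, ncol(Y), deriveSeed(seed, "init"))
  st <- .adamInit(params)
  n <- nrow(X)
  hist <- data.frame(epoch = integer(0), loss = numeric(0))
  best <- Inf; bad <- 0L
  for (ep in seq_len(maxEpochs)) {
    ord <- .withSeed(deriveSeed(seed, paste0("shuffle", ep)), sample.int(n))
    tot <- 0
    for (start in seq(1L, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, n)]
      lg <- .denseLossGrad(params, X[idx, , drop = FALSE],
                           Y[idx, , drop = FALSE], outputType)
      up <- .adamStep(params, lg$grads, st, lr, beta1, beta2)
      params <- up$params; st <- up$state
      tot <- tot + lg$loss * length(idx)
    }
    epochLoss <- tot / n
    hist <- rbind(hist, data.frame(epoch = ep, loss = epochLoss))
    if (verbose && ep %% 10 == 0)
      message(sprintf("epoch %d: loss %.6f", ep, epochLoss))
    if (patience > 0L) {  # optional early stopping, off by default
      if (epochLoss < best - 1e-6) { best <- epochLoss; bad <- 0L }
      else if ((bad <- bad + 1L) >= patience) break
    }
  }
  params$center <- center
  list(params = params, history = hist)
}
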
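## Transformer encoder for AU sequence classification.
##
## Architecture: linear projection of the per-frame AU vector to the
## embedding dimension, summed with fixed sinusoidal positional
## encodings, then `numLayers` post-norm encoder blocks (multi-head
## self-attention + add&norm, position-wise feed-forward + add&norm),
## and an MLP head applied to the representation of the last non-padded
## frame, ending in a single logistic unit (pain probability).
## All gradients are hand-derived; the test suite checks them against
## central finite differences and checks the attention weights against a
## brute-force softmax oracle.

.peMatrix <- function(T, d) {
  pos <- matrix(seq_len(T) - 1, T, d)
  i <- matrix(rep(seq_len(d) - 1, each = T), T, d)
  angle <- pos / 10000^((i %/% 2) * 2 / d)
  ifelse(i %% 2 == 0, sin(angle), cos(angle))
}

.xavier <- function(fin, fout)
  matrix(stats::rnorm(fin * fout, 0, sqrt(2 / (fin + fout))), fin, fout)

.tfInit <- function(cfg) {
  .withSeed(deriveSeed(cfg$seed, "tf-init"), {
    d <- cfg$projectionDim
    p <- list(Wp = .xavier(cfg$naInput, d), bp = numeric(d))
    for (l in seq_len(cfg$numLayers)) {
      pre <- paste0("L", l, ".")
      p[[paste0(pre, "Wq")]] <- .xavier(d, d)
      p[[paste0(pre, "Wk")]] <- .xavier(d, d)
      p[[paste0(pre, "Wv")]] <- .xavier(d, d)
      p[[paste0(pre, "Wo")]] <- .xavier(d, d)
      p[[paste0(pre, "bq")]] <- numeric(d)
      p[[paste0(pre, "bk")]] <- numeric(d)
      p[[paste0(pre, "bv")]] <- numeric(d)
      p[[paste0(pre, "bo")]] <- numeric(d)
      p[[paste0(pre, "g1")]] <- rep(1, d)
      p[[paste0(pre, "be1")]] <- numeric(d)
      p[[paste0(pre, "Wf1")]] <- .xavier(d, cfg$ffDim)
      p[[paste0(pre, "bf1")]] <- numeric(cfg$ffDim)
      p[[paste0(pre, "Wf2")]] <- .xavier(cfg$ffDim, d)
      p[[paste0(pre, "bf2")]] <- numeric(d)
      p[[paste0(pre, "g2")]] <- rep(1, d)
      p[[paste0(pre, "be2")]] <- numeric(d)
    }
    p$head.Wh <- .xavier(d, cfg$mlpHidden)
    p$head.bh <- numeric(cfg$mlpHidden)
    p$head.Wo <- .xavier(cfg$mlpHidden, 1L)
    p$head.bo <- 0
    p
  })
}

## Row-wise layer norm; returns output plus backward cache.
.lnForward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  invstd <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * invstd
  list(Y = sweep(xhat, 2, g, `*`) + rep(b, each = nrow(X)),
       xhat = xhat, invstd = invstd)
}

.lnBackward <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$invstd * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

## Multi-head self-attention forward for one window.
.mhaForward <- function(X, p, pre, valid, numHeads) {
  d <- ncol(X); dk <- d %/% numHeads
  Q <- sweep(X %*% p[[paste0(pre, "Wq")]], 2, p[[paste0(pre, "bq")]], `+`)
  K <- sweep(X %*% p[[paste0(pre, "Wk")]], 2, p[[paste0(pre, "bk")]], `+`)
  V <- sweep(X %*% p[[paste0(pre, "Wv")]], 2, p[[paste0(pre, "bv")]], `+`)
  O <- matrix(0, nrow(X), d)
  P <- vector("list", numHeads)
  for (h in seq_len(numHeads)) {
    ix <- ((h - 1) * dk + 1):(h * dk)
    S <- tcrossprod(Q[, ix, drop = FALSE], K[, ix, drop = FALSE]) / sqrt(dk)
    S[, !valid] <- -Inf
    S <- S - apply(S, 1, max)           # row-stable softmax
    E <- exp(S)
    P[[h]] <- E / rowSums(E)
    O[, ix] <- P[[h]] %*% V[, ix, drop = FALSE]
  }
  out <- sweep(O %*% p[[paste0(pre, "Wo")]], 2, p[[paste0(pre, "bo")]], `+`)
  list(out = out, Q = Q, K = K, V = V, O = O, P = P)
}

.mhaBackward <- function(dOut, cache, X, p, pre, numHeads, grads) {
  d <- ncol(X); dk <- d %/% numHeads
  grads[[paste0(pre, "Wo")]] <- grads[[paste0(pre, "Wo")]] +
    crossprod(cache$O, dOut)
  grads[[paste0(pre, "bo")]] <- grads[[paste0(pre, "bo")]] + colSums(dOut)
  dO <- tcrossprod(dOut, p[[paste0(pre, "Wo")]])
  dQ <- dK <- dV <- matrix(0, nrow(X), d)
  for (h in seq_len(numHeads)) {
    ix <- ((h - 1) * dk + 1):(h * dk)
    Ph <- cache$P[[h]]
    dOh <- dO[, ix, drop = FALSE]
    dP <- tcrossprod(dOh, cache$V[, ix, drop = FALSE])
    dS <- Ph * (dP - rowSums(dP * Ph))
    dQ[, ix] <- dS %*% cache$K[, ix, drop = FALSE] / sqrt(dk)
    dK[, ix] <- crossprod(dS, cache$Q[, ix, drop = FALSE]) / sqrt(dk)
    dV[, ix] <- crossprod(Ph, dOh)
  }
  for (nm in c("q", "k", "v")) {
    dM <- switch(nm, q = dQ, k = dK, v = dV)
    grads[[paste0(pre, "W", nm)]] <- grads[[paste0(pre, "W", nm)]] +
      crossprod(X, dM)
    grads[[paste0(pre, "b", nm)]] <- grads[[paste0(pre, "b", nm)]] +
      colSums(dM)
  }
  dX <- tcrossprod(dQ, p[[paste0(pre, "Wq")]]) +
    tcrossprod(dK, p[[paste0(pre, "Wk")]]) +
    tcrossprod(dV, p[[paste0(pre, "Wv")]])
  list(dX = dX, grads = grads)
}

## Full encoder forward for one window. A: T x Na, valid: logical T.
## Returns Z (T x d) and caches for backprop.
.tfForward <- function(A, p, cfg, valid = rep(TRUE, nrow(A))) {
  if (!any(valid))
    return(list(Z = matrix(0, nrow(A), cfg$projectionDim), degenerate = TRUE))
  X <- sweep(A %*% p$Wp, 2, p$bp, `+`) + .peMatrix(nrow(A), cfg$projectionDim)
  layers <- vector("list", cfg$numLayers)
  for (l in seq_len(cfg$numLayers)) {
    pre <- paste0("L", l, ".")
    att <- .mhaForward(X, p, pre, valid, cfg$numHeads)
    a <- X + att$out
    ln1 <- .lnForward(a, p[[paste0(pre, "g1")]], p[[paste0(pre, "be1")]])
    X1 <- ln1$Y
    Fh <- pmax(sweep(X1 %*% p[[paste0(pre, "Wf1")]], 2,
                     p[[paste0(pre, "bf1")]], `+`), 0)
    b <- X1 + sweep(Fh %*% p[[paste0(pre, "Wf2")]], 2,
                    p[[paste0(pre, "bf2")]], `+`)
    ln2 <- .lnForward(b, p[[paste0(pre, "g2")]], p[[paste0(pre, "be2")]])
    layers[[l]] <- list(Xin = X, att = att, ln1 = ln1, X1 = X1, Fh = Fh,
                        ln2 = ln2)
    X <- ln2$Y
  }
  list(Z = X, layers = layers, valid = valid, A = A, degenerate = FALSE)
}

## Head forward: probability from the last valid position of Z.
.tfHead <- function(Z, p, valid, dropMask = NULL) {
  zlast <- if (any(valid)) Z[max(which(valid)), ] else numeric(ncol(Z))
  H <- pmax(drop(zlast %*% p$head.Wh) + p$head.bh, 0)
  if (!is.null(dropMask)) H <- H * dropMask
  z <- sum(H * p$head.Wo) + p$head.bo
  list(prob = stats::plogis(z), z = z, H = H, zlast = zlast)
}

## Backward pass for one window; returns gradient contribution list.
.tfBackward <- function(fw, hd, y, p, cfg, dropMask = NULL) {
  grads <- lapply(p, function(x) x * 0)
  dz <- hd$prob - y                        # BCE on the logit
  grads$head.bo <- dz
  grads$head.Wo <- matrix(hd$H * dz, ncol = 1)
  dH <- dz * drop(p$head.Wo)
  if (!is.null(dropMask)) dH <- dH * dropMask
  dH[hd$H == 0] <- 0
  grads$head.Wh <- outer(hd$zlast, dH)
  grads$head.bh <- dH
  dZ <- matrix(0, nrow(fw$Z), ncol(fw$Z))
  dZ[max(which(fw$valid)), ] <- drop(p$head.Wh %*% dH)
  for (l in rev(seq_len(cfg$numLayers))) {
    pre <- paste0("L", l, ".")
    lc <- fw$layers[[l]]
    ln2b <- .lnBackward(dZ, lc$ln2, p[[paste0(pre, "g2")]])
    grads[[paste0(pre, "g2")]] <- grads[[paste0(pre, "g2")]] + ln2b$dg
    grads[[paste0(pre, "be2")]] <- grads[[paste0(pre, "be2")]] + ln2b$db
    db <- ln2b$dX
    ## feed-forward branch
    dFF <- db
    dFh <- tcrossprod(dFF, p[[paste0(pre, "Wf2")]])
    dFh[lc$Fh == 0] <- 0
    grads[[paste0(pre, "Wf2")]] <- grads[[paste0(pre, "Wf2")]] +
      crossprod(lc$Fh, dFF)
    grads[[paste0(pre, "bf2")]] <- grads[[paste0(pre, "bf2")]] + colSums(dFF)
    grads[[paste0(pre, "Wf1")]] <- grads[[paste0(pre, "Wf1")]] +
      crossprod(lc$X1, dFh)
    grads[[paste0(pre, "bf1")]] <- grads[[paste0(pre, "bf1")]] + colSums(dFh)
    dX1 <- db + tcrossprod(dFh, p[[paste0(pre, "Wf1")]])
    ln1b <- .lnBackward(dX1, lc$ln1, p[[paste0(pre, "g1")]])
    grads[[paste0(pre, "g1")]] <- grads[[paste0(pre, "g1")]] + ln1b$dg
    grads[[paste0(pre, "be1")]] <- grads[[paste0(pre, "be1")]] + ln1b$db
    da <- ln1b$dX
    mb <- .mhaBackward(da, lc$att, lc$Xin, p, pre, cfg$numHeads, grads)
    grads <- mb$grads
    dZ <- da + mb$dX                       # residual + attention path
  }
  grads$Wp <- grads$Wp + crossprod(fw$A, dZ)
  grads$bp <- grads$bp + colSums(dZ)
  grads
}

## Loss + gradients over a batch of windows (list of list(A, valid, y)).
.tfBatchGrad <- function(p, cfg, batch, dropSeed = NULL) {
  grads <- lapply(p, function(x) x * 0)
  loss <- 0
  for (i in seq_along(batch)) {
    w <- batch[[i]]
    fw <- .tfForward(w$A, p, cfg, w$valid)
    dropMask <- NULL
    if (!is.null(dropSeed) && cfg$dropout > 0)
      dropMask <- .withSeed(deriveSeed(dropSeed, i),
        (stats::runif(cfg$mlpHidden) >= cfg$dropout) / (1 - cfg$dropout))
    if (fw$degenerate) next
    hd <- .tfHead(fw$Z, p, w$valid, dropMask)
    eps <- 1e-12
    loss <- loss - (w$y * log(hd$prob + eps) +
                    (1 - w$y) * log(1 - hd$prob + eps))
    g <- .tfBackward(fw, hd, w$y, p, cfg, dropMask)
    for (k in names(grads)) grads[[k]] <- grads[[k]] + g[[k]]
  }
  n <- length(batch)
  list(loss = loss / n, grads = lapply(grads, function(g) g / n))
}
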
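## Two-layer LSTM pain classifier with a logistic head on the hidden
## state at each window's last non-padded frame. Forward and
## backpropagation-through-time are hand-derived (gate order i, f, g, o)
## and checked against finite differences in the test suite.
## Batched over windows: states are B x H matrices per time step.

.lstmInit <- function(cfg) {
  .withSeed(deriveSeed(cfg$seed, "lstm-init"), {
    H <- cfg$hiddenDim
    p <- list()
    ins <- c(cfg$naInput, rep(H, cfg$numLayers - 1L))
    for (l in seq_len(cfg$numLayers)) {
      p[[paste0("L", l, ".Wx")]] <- .xavier(ins[l], 4L * H)
      p[[paste0("L", l, ".Wh")]] <- .xavier(H, 4L * H)
      b <- numeric(4L * H)
      b[(H + 1L):(2L * H)] <- 1       # forget-gate bias init
      p[[paste0("L", l, ".b")]] <- b
    }
    p$head.Wo <- .xavier(H, 1L)
    p$head.bo <- 0
    p
  })
}

## X: T x B x Na array; returns per-layer caches and final hidden states.
.lstmForward <- function(X, p, cfg) {
  Tn <- dim(X)[1]; B <- dim(X)[2]; H <- cfg$hiddenDim
  inp <- X
  layers <- vector("list", cfg$numLayers)
  for (l in seq_len(cfg$numLayers)) {
    Wx <- p[[paste0("L", l, ".Wx")]]
    Wh <- p[[paste0("L", l, ".Wh")]]
    b <- p[[paste0("L", l, ".b")]]
    h <- matrix(0, B, H); cs <- matrix(0, B, H)
    cache <- vector("list", Tn)
    Hout <- array(0, c(Tn, B, H))
    for (t in seq_len(Tn)) {
      Xt <- matrix(inp[t, , ], B)
      Z <- Xt %*% Wx + h %*% Wh + rep(b, each = B)
      ig <- stats::plogis(Z[, 1:H, drop = FALSE])
      fg <- stats::plogis(Z[, (H + 1):(2 * H), drop = FALSE])
      gg <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
      og <- stats::plogis(Z[, (3 * H + 1):(4 * H), drop = FALSE])
      cNew <- fg * cs + ig * gg
      tc <- tanh(cNew)
      hNew <- og * tc
      cache[[t]] <- list(Xt = Xt, hPrev = h, cPrev = cs, i = ig, f = fg,
                         g = gg, o = og, tc = tc)
      h <- hNew; cs <- cNew
      Hout[t, , ] <- hNew
    }
    layers[[l]] <- list(cache = cache, Hout = Hout)
    inp <- Hout
  }
  layers
}

## Batched loss + grads. batch: list of list(A = T x Na, valid, y).
.lstmBatchGrad <- function(p, cfg, batch) {
  B <- length(batch)
  Tn <- nrow(batch[[1]]$A)
  X <- array(0, c(Tn, B, cfg$naInput))
  for (b in seq_len(B)) X[, b, ] <- batch[[b]]$A
  lastValid <- vapply(batch, function(w)
    if (any(w$valid)) max(which(w$valid)) else 0L, integer(1))
  y <- vapply(batch, function(w) w$y, numeric(1))
  layers <- .lstmForward(X, p, cfg)
  H <- cfg$hiddenDim
  top <- layers[[cfg$numLayers]]$Hout
  hfin <- matrix(0, B, H)
  for (b in seq_len(B)) if (lastValid[b] > 0) hfin[b, ] <- top[lastValid[b], b, ]
  z <- drop(hfin %*% p$head.Wo) + p$head.bo
  prob <- stats::plogis(z)
  eps <- 1e-12
  loss <- -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
  dz <- (prob - y) / B
  grads <- lapply(p, function(x) x * 0)
  grads$head.Wo <- crossprod(hfin, matrix(dz, ncol = 1))
  grads$head.bo <- sum(dz)
  ## gradient injected into the top layer at each window's last frame
  dInject <- array(0, c(Tn, B, H))
  for (b in seq_len(B)) if (lastValid[b] > 0)
    dInject[lastValid[b], b, ] <- dz[b] * drop(p$head.Wo)
  for (l in rev(seq_len(cfg$numLayers))) {
    Wx <- p[[paste0("L", l, ".Wx")]]
    Wh <- p[[paste0("L", l, ".Wh")]]
    cache <- layers[[l]]$cache
    dWx <- Wx * 0; dWh <- Wh * 0; db <- numeric(4 * H)
    dhNext <- matrix(0, B, H); dcNext <- matrix(0, B, H)
    dBelow <- if (l > 1) array(0, dim(layers[[l - 1]]$Hout)) else NULL
    for (t in rev(seq_len(Tn))) {
      cc <- cache[[t]]
      dh <- dhNext + matrix(dInject[t, , ], B)
      dc <- dcNext + dh * cc$o * (1 - cc$tc^2)
      dZ <- cbind(dc * cc$g * cc$i * (1 - cc$i),
                  dc * cc$cPrev * cc$f * (1 - cc$f),
                  dc * cc$i * (1 - cc$g^2),
                  dh * cc$tc * cc$o * (1 - cc$o))
      dWx <- dWx + crossprod(cc$Xt, dZ)
      dWh <- dWh + crossprod(cc$hPrev, dZ)
      db <- db + colSums(dZ)
      if (l > 1) dBelow[t, , ] <- dZ %*% t(Wx)
      dhNext <- dZ %*% t(Wh)
      dcNext <- dc * cc$f
    }
    grads[[paste0("L", l, ".Wx")]] <- dWx
    grads[[paste0("L", l, ".Wh")]] <- dWh
    grads[[paste0("L", l, ".b")]] <- db
    if (l > 1) dInject <- dBelow
  }
  list(loss = loss, grads = grads, prob = prob)
}
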
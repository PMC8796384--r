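# Network internals: span-relative 1D convolutions (ordinary zero-padded or
# circular), batch normalization, max pooling over the occupied span, fully
# connected stack, backpropagation and Adam. All computation is done on
# homogeneous batches (samples sharing the same span length n), stored as
# C x n x B arrays.

.BN_EPS <- 1e-5

# Receptive-field index map: k x n matrix of input positions for each output
# position; 0 encodes the zero-padding column.
.convIndex <- function(n, k, kind) {
  pad <- (k - 1L) %/% 2L
  idx <- matrix(0L, k, n)
  for (t in seq_len(k)) {
    v <- seq_len(n) + (t - 1L) - pad
    if (kind == "cyclic") {
      idx[t, ] <- ((v - 1L) %% n) + 1L
    } else {
      v[v < 1L | v > n] <- 0L
      idx[t, ] <- v
    }
  }
  idx
}

# Gather patches: X3 (Cin, n, B) -> (Cin*k, n*B) matrix.
.gatherPatches <- function(X3, idx) {
  d <- dim(X3)
  Cin <- d[1]; n <- d[2]; B <- d[3]
  k <- nrow(idx)
  Xz <- array(0, c(Cin, n + 1L, B))
  Xz[, seq_len(n), ] <- X3
  idxz <- idx
  idxz[idxz == 0L] <- n + 1L
  P <- array(0, c(Cin * k, n, B))
  for (t in seq_len(k))
    P[((t - 1L) * Cin + 1L):(t * Cin), , ] <- Xz[, idxz[t, ], , drop = FALSE]
  list(P = matrix(P, Cin * k, n * B), idxz = idxz)
}

# Scatter-add patch gradients back onto the input: inverse of .gatherPatches.
.scatterPatches <- function(dP, idxz, Cin, n, B) {
  k <- nrow(idxz)
  dP3 <- array(dP, c(Cin * k, n, B))
  dXz <- array(0, c(Cin, n + 1L, B))
  for (t in seq_len(k)) {
    block <- dP3[((t - 1L) * Cin + 1L):(t * Cin), , , drop = FALSE]
    cols <- idxz[t, ]
    dXz[, cols, ] <- dXz[, cols, , drop = FALSE] + block
  }
  dXz[, seq_len(n), , drop = FALSE]
}

.bnForward <- function(Z, layer, training, momentum = 0.1) {
  if (training) {
    mu <- rowMeans(Z)
    v <- rowMeans(Z * Z) - mu * mu
    v[v < 0] <- 0
    invstd <- 1 / sqrt(v + .BN_EPS)
    xhat <- (Z - mu) * invstd
    newStats <- list(
      rmean = (1 - momentum) * layer$rmean + momentum * mu,
      rvar = (1 - momentum) * layer$rvar + momentum * v
    )
  } else {
    invstd <- 1 / sqrt(layer$rvar + .BN_EPS)
    xhat <- (Z - layer$rmean) * invstd
    newStats <- NULL
  }
  list(out = xhat * layer$gamma + layer$beta, xhat = xhat, invstd = invstd,
       newStats = newStats)
}

.bnBackward <- function(dout, cache, layer, training) {
  dgamma <- rowSums(dout * cache$xhat)
  dbeta <- rowSums(dout)
  dxhat <- dout * layer$gamma
  if (training) {
    m <- ncol(dout)
    dZ <- (cache$invstd / m) *
      (m * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  } else {
    dZ <- dxhat * cache$invstd
  }
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

.activate <- function(Z, activation) {
  if (activation == "relu") pmax(Z, 0) else Z
}

.activateBackward <- function(dA, Z, activation) {
  if (activation == "relu") dA * (Z > 0) else dA
}

# Full forward pass on a homogeneous batch.
# X3: array (D, P, B) where P = span length (conv/max path) or L (flatten).
# Returns list(yhat, cache, statsUpdates).
.netForward <- function(params, cfg, X3, training = FALSE) {
  d <- dim(X3)
  B <- d[3]
  cache <- list(convs = list(), fcs = list())
  H <- X3
  statsUpdates <- list(conv = list(), fc = list())
  for (l in seq_along(cfg$convLayers)) {
    spec <- cfg$convLayers[[l]]
    k <- spec$kernel
    Cin <- dim(H)[1]; n <- dim(H)[2]
    if (cfg$convKind == "cyclic" && k > n)
      stop("kernel larger than ring: kernel size ", k, " exceeds span ", n)
    idx <- .convIndex(n, k, cfg$convKind)
    gp <- .gatherPatches(H, idx)
    ly <- params$conv[[l]]
    Z <- ly$W %*% gp$P + ly$b
    if (cfg$batchNorm) {
      bn <- .bnForward(Z, ly, training, cfg$bnMomentum)
      A <- .activate(bn$out, cfg$activation)
      if (training) statsUpdates$conv[[l]] <- bn$newStats
    } else {
      bn <- NULL
      A <- .activate(Z, cfg$activation)
    }
    cache$convs[[l]] <- list(P = gp$P, idxz = gp$idxz, Z = Z, bn = bn,
                             Cin = Cin, n = n, preact = if (cfg$batchNorm) bn$out else Z)
    H <- array(A, c(spec$channels, n, B))
  }
  # pooling
  dH <- dim(H)
  C <- dH[1]; P <- dH[2]
  if (cfg$pooling == "max") {
    M <- matrix(aperm(H, c(2L, 1L, 3L)), P, C * B)  # positions x (channel, sample)
    best <- M[1L, ]
    amax <- rep(1L, C * B)
    if (P > 1L) for (j in 2:P) {
      upd <- M[j, ] > best
      best[upd] <- M[j, upd]
      amax[upd] <- j
    }
    x <- matrix(best, C, B)
    cache$pool <- list(kind = "max", amax = amax, C = C, P = P, B = B)
  } else {  # flatten
    x <- matrix(H, C * P, B)
    cache$pool <- list(kind = "flatten", C = C, P = P, B = B)
  }
  # fully connected stack
  nfc <- length(params$fc)
  for (m in seq_len(nfc)) {
    ly <- params$fc[[m]]
    Z <- ly$W %*% x + ly$b
    last <- (m == nfc)
    if (!last && cfg$batchNorm) {
      bn <- .bnForward(Z, ly, training, cfg$bnMomentum)
      A <- .activate(bn$out, cfg$activation)
      if (training) statsUpdates$fc[[m]] <- bn$newStats
    } else if (!last) {
      bn <- NULL
      A <- .activate(Z, cfg$activation)
    } else {
      bn <- NULL
      A <- Z
    }
    cache$fcs[[m]] <- list(x = x, Z = Z, bn = bn,
                           preact = if (!last && cfg$batchNorm) bn$out else Z)
    x <- A
  }
  list(yhat = as.numeric(x), cache = cache, statsUpdates = statsUpdates)
}

# Backward pass; dy is the gradient at the scalar output (length B).
# Returns list(grads, dX) where dX matches the forward input array.
.netBackward <- function(params, cfg, cache, dy, training = FALSE,
                         needInputGrad = FALSE) {
  grads <- list(conv = list(), fc = list())
  B <- cache$pool$B
  dx <- matrix(dy, 1L, B)
  nfc <- length(params$fc)
  for (m in rev(seq_len(nfc))) {
    ly <- params$fc[[m]]
    cc <- cache$fcs[[m]]
    last <- (m == nfc)
    if (!last) {
      dA <- .activateBackward(dx, cc$preact, cfg$activation)
      if (cfg$batchNorm) {
        bb <- .bnBackward(dA, cc$bn, ly, training)
        dZ <- bb$dZ
        grads$fc[[m]] <- list(W = dZ %*% t(cc$x), b = rowSums(dZ),
                              gamma = bb$dgamma, beta = bb$dbeta)
      } else {
        dZ <- dA
        grads$fc[[m]] <- list(W = dZ %*% t(cc$x), b = rowSums(dZ))
      }
    } else {
      dZ <- dx
      grads$fc[[m]] <- list(W = dZ %*% t(cc$x), b = rowSums(dZ))
    }
    dx <- t(ly$W) %*% dZ
  }
  # pooling backward
  pl <- cache$pool
  if (pl$kind == "max") {
    dH <- array(0, c(pl$C, pl$P, pl$B))
    cb <- as.vector(dx)  # (C * B)
    ci <- rep(seq_len(pl$C), times = pl$B)
    bi <- rep(seq_len(pl$B), each = pl$C)
    flat <- ci + (pl$amax - 1L) * pl$C + (bi - 1L) * pl$C * pl$P
    dH[flat] <- cb
  } else {
    dH <- array(dx, c(pl$C, pl$P, pl$B))
  }
  # conv stack backward
  for (l in rev(seq_along(cfg$convLayers))) {
    spec <- cfg$convLayers[[l]]
    cc <- cache$convs[[l]]
    ly <- params$conv[[l]]
    n <- cc$n
    dA <- matrix(dH, spec$channels, n * B)
    dA <- .activateBackward(dA, cc$preact, cfg$activation)
    if (cfg$batchNorm) {
      bb <- .bnBackward(dA, cc$bn, ly, training)
      dZ <- bb$dZ
      grads$conv[[l]] <- list(W = dZ %*% t(cc$P), b = rowSums(dZ),
                              gamma = bb$dgamma, beta = bb$dbeta)
    } else {
      dZ <- dA
      grads$conv[[l]] <- list(W = dZ %*% t(cc$P), b = rowSums(dZ))
    }
    if (l > 1L || needInputGrad) {
      dP <- t(ly$W) %*% dZ
      dH <- .scatterPatches(dP, cc$idxz, cc$Cin, n, B)
    }
  }
  dX <- if (needInputGrad || length(cfg$convLayers) == 0L) dH else NULL
  list(grads = grads, dX = dX)
}

# Adam: walk the trainable leaves (W, b, gamma, beta) of the nested params.
.adamInit <- function(params) {
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    list(m = x * 0, v = x * 0)
  }
  lapply(params, function(grp) lapply(grp, function(ly) {
    tr <- ly[names(ly) %in% c("W", "b", "gamma", "beta")]
    lapply(tr, function(p) list(m = p * 0, v = p * 0))
  }))
}

.adamStep <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (grp in names(grads)) {
    for (l in seq_along(grads[[grp]])) {
      g <- grads[[grp]][[l]]
      for (p in names(g)) {
        st <- state[[grp]][[l]][[p]]
        st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
        st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
        mhat <- st$m / (1 - beta1^t)
        vhat <- st$v / (1 - beta2^t)
        params[[grp]][[l]][[p]] <- params[[grp]][[l]][[p]] -
          lr * mhat / (sqrt(vhat) + eps)
        state[[grp]][[l]][[p]] <- st
      }
    }
  }
  list(params = params, state = state)
}

.applyStatsUpdates <- function(params, statsUpdates) {
  for (grp in c("conv", "fc")) {
    for (l in seq_along(statsUpdates[[grp]])) {
      su <- statsUpdates[[grp]][[l]]
      if (!is.null(su)) {
        params[[grp]][[l]]$rmean <- su$rmean
        params[[grp]][[l]]$rvar <- su$rvar
      }
    }
  }
  params
}
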
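# Internal neural-network engine: 1-D valid convolution, dense blocks with
# batch normalization / activation / dropout, softmax head(s), Adam on
# categorical cross-entropy.  Everything is plain matrix algebra so the
# heavy lifting lands in BLAS.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

activationFun <- function(name) {
  switch(name,
    tanh = list(f = tanh,
                df = function(z, a) 1 - a * a),
    sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                   df = function(z, a) a * (1 - a)),
    relu = list(f = function(z) pmax(z, 0),
                df = function(z, a) (z > 0) * 1),
    elu = list(f = function(z) pmax(z, 0) + expm1(pmin(z, 0)),
               df = function(z, a) { pos <- z > 0; pos + (!pos) * (a + 1) }),
    linear = list(f = identity, df = function(z, a) 1),
    stop(sprintf("unknown activation '%s'", name), call. = FALSE))
}

# Glorot-uniform initial weights
glorotInit <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

initBranch <- function(spec) {
  p <- list()
  inDim <- spec$inputLength
  if (spec$useConv) {
    p$convW <- glorotInit(spec$convKernel, spec$convFilters)
    p$convB <- numeric(spec$convFilters)
    inDim <- (spec$inputLength - spec$convKernel + 1L) * spec$convFilters
  }
  p$dense <- vector("list", length(spec$denseSizes))
  for (i in seq_along(spec$denseSizes)) {
    out <- spec$denseSizes[i]
    layer <- list(W = glorotInit(inDim, out), b = numeric(out))
    if (spec$batchNorm) {
      layer$gamma <- rep(1, out)
      layer$beta <- numeric(out)
      layer$runMean <- numeric(out)
      layer$runVar <- rep(1, out)
    }
    p$dense[[i]] <- layer
    inDim <- out
  }
  p
}

# columns of the valid 1-D convolution, one filter at a time
convForward <- function(X, convW, convB) {
  k <- nrow(convW); f <- ncol(convW)
  L <- ncol(X); Lc <- L - k + 1L
  out <- matrix(0, nrow(X), Lc * f)
  for (j in seq_len(f)) {
    block <- matrix(convB[j], nrow(X), Lc)
    for (t in seq_len(k))
      block <- block + convW[t, j] * X[, t:(t + Lc - 1L), drop = FALSE]
    out[, ((j - 1L) * Lc + 1L):(j * Lc)] <- block
  }
  out
}

convBackward <- function(X, dPre, k, f) {
  Lc <- ncol(X) - k + 1L
  dW <- matrix(0, k, f)
  dB <- numeric(f)
  for (j in seq_len(f)) {
    block <- dPre[, ((j - 1L) * Lc + 1L):(j * Lc), drop = FALSE]
    dB[j] <- sum(block)
    for (t in seq_len(k))
      dW[t, j] <- sum(block * X[, t:(t + Lc - 1L), drop = FALSE])
  }
  list(convW = dW, convB = dB)
}

addRow <- function(M, v) M + rep(v, each = nrow(M))

forwardBranch <- function(params, spec, X, training = FALSE) {
  cache <- list(X = X)
  H <- X
  if (spec$useConv) {
    act <- activationFun(spec$convActivation)
    Z <- convForward(X, params$convW, params$convB)
    A <- act$f(Z)
    cache$convZ <- Z; cache$convA <- A
    H <- A
  }
  act <- activationFun(spec$denseActivation)
  caches <- vector("list", length(params$dense))
  for (i in seq_along(params$dense)) {
    ly <- params$dense[[i]]
    c_i <- list(Hin = H)
    Z <- addRow(H %*% ly$W, ly$b)
    if (spec$batchNorm) {
      if (training) {
        mu <- colMeans(Z)
        va <- colMeans(Z * Z) - mu * mu
        va <- pmax(va, 0)
        c_i$mu <- mu; c_i$va <- va
      } else {
        mu <- ly$runMean; va <- ly$runVar
      }
      Zhat <- addRow(Z, -mu) / rep(sqrt(va + BN_EPS), each = nrow(Z))
      Y <- addRow(Zhat * rep(ly$gamma, each = nrow(Z)), ly$beta)
      c_i$Zhat <- Zhat
    } else {
      Y <- Z
    }
    c_i$Y <- Y
    A <- act$f(Y)
    c_i$A <- A
    if (training && spec$dropout > 0) {
      mask <- matrix((stats::runif(length(A)) >= spec$dropout) /
                       (1 - spec$dropout), nrow(A), ncol(A))
      A <- A * mask
      c_i$mask <- mask
    }
    c_i$out <- A
    caches[[i]] <- c_i
    H <- A
  }
  list(out = H, cache = list(conv = cache, dense = caches))
}

backwardBranch <- function(params, spec, cache, dOut) {
  act <- activationFun(spec$denseActivation)
  grads <- list(dense = vector("list", length(params$dense)))
  dH <- dOut
  for (i in rev(seq_along(params$dense))) {
    ly <- params$dense[[i]]
    c_i <- cache$dense[[i]]
    dA <- dH
    if (!is.null(c_i$mask)) dA <- dA * c_i$mask
    dY <- dA * act$df(c_i$Y, c_i$A)
    g <- list()
    if (spec$batchNorm) {
      n <- nrow(dY)
      g$gamma <- colSums(dY * c_i$Zhat)
      g$beta <- colSums(dY)
      dZhat <- dY * rep(ly$gamma, each = n)
      mZ <- colMeans(dZhat)
      mZZ <- colMeans(dZhat * c_i$Zhat)
      dZ <- (dZhat - rep(mZ, each = n) - c_i$Zhat * rep(mZZ, each = n)) /
        rep(sqrt(c_i$va + BN_EPS), each = n)
    } else {
      dZ <- dY
    }
    g$W <- crossprod(c_i$Hin, dZ)
    g$b <- colSums(dZ)
    dH <- tcrossprod(dZ, ly$W)
    grads$dense[[i]] <- g
  }
  if (spec$useConv) {
    cact <- activationFun(spec$convActivation)
    dPre <- dH * cact$df(cache$conv$convZ, cache$conv$convA)
    cg <- convBackward(cache$conv$X, dPre, spec$convKernel, spec$convFilters)
    grads$convW <- cg$convW
    grads$convB <- cg$convB
  }
  grads
}

# update batch-norm running statistics from the caches of one batch
updateRunningStats <- function(params, spec, cache) {
  if (!spec$batchNorm) return(params)
  for (i in seq_along(params$dense)) {
    c_i <- cache$dense[[i]]
    params$dense[[i]]$runMean <-
      BN_MOMENTUM * params$dense[[i]]$runMean + (1 - BN_MOMENTUM) * c_i$mu
    params$dense[[i]]$runVar <-
      BN_MOMENTUM * params$dense[[i]]$runVar + (1 - BN_MOMENTUM) * c_i$va
  }
  params
}

softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Adam moment state mirroring a gradient structure
adamInit <- function(g) {
  if (is.list(g)) return(lapply(g, adamInit))
  list(m = g * 0, v = g * 0)
}

adamUpdate <- function(params, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  step <- function(p, g, s) {
    if (is.list(g)) {
      keys <- if (is.null(names(g))) seq_along(g) else names(g)
      for (nm in keys) {
        if (is.null(g[[nm]])) next
        r <- step(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- r$p; s[[nm]] <- r$s
      }
      return(list(p = p, s = s))
    }
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), s = s)
  }
  step(params, grads, state)
}
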
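# Minimal dense/convolutional network engine on BLAS matrix operations:
# affine layers, batch normalization, ReLU, and the Adam optimizer, with
# hand-derived backward passes.  Deterministic given seeds; CPU-only by
# design (the models here are tiny).

# fast per-column broadcast helpers (avoid sweep() overhead in hot paths)
rowAdd <- function(X, b) X + rep(b, each = nrow(X))
rowScale <- function(X, s) X * rep(s, each = nrow(X))

nnInitMatrix <- function(nIn, nOut) {
  # He-normal initialization for ReLU networks
  matrix(stats::rnorm(nIn * nOut, 0, sqrt(2 / nIn)), nIn, nOut)
}

# Affine layer ---------------------------------------------------------------

affineForward <- function(X, W, b) {
  list(Y = rowAdd(X %*% W, b), X = X)
}

affineBackward <- function(cache, W, dY) {
  list(dX = dY %*% t(W),
       dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

# ReLU ------------------------------------------------------------------------

reluForward <- function(X) list(Y = pmax(X, 0))

reluBackward <- function(cache, dY) dY * (cache$Y > 0)

# Batch normalization ---------------------------------------------------------
# Per-channel (column) normalization; biased variance, as is conventional.
# `state` carries running statistics for inference mode.

bnForward <- function(X, gamma, beta, state, training, momentum = 0.1,
                      eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    xc <- rowAdd(X, -mu)
    v <- colMeans(xc^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
    xc <- rowAdd(X, -mu)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- rowScale(xc, invstd)
  Y <- rowAdd(rowScale(xhat, gamma), beta)
  list(Y = Y, xhat = xhat, invstd = invstd, state = state)
}

bnBackward <- function(cache, gamma, dY) {
  N <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- rowScale(dY, gamma)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dX <- rowScale(rowAdd(dxhat, -s1 / N) - rowScale(xhat, s2 / N),
                 cache$invstd)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

bnStateInit <- function(nCh) {
  env <- new.env(parent = emptyenv())
  env$mean <- numeric(nCh)
  env$var <- rep(1, nCh)
  env
}

bnStateClone <- function(state) {
  env <- new.env(parent = emptyenv())
  env$mean <- state$mean
  env$var <- state$var
  env
}

# Adam ------------------------------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8, trainable = NULL) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    if (!is.null(trainable) && !(nm %in% trainable)) next
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Gradient accumulation over network branches.
addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}
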
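# Internal dense-layer primitives with explicit forward caches and analytic
# backward passes.  Shapes follow the (cells x features) convention; all
# parameters live in a flat named list so the optimizer can treat them
# uniformly.

# broadcast a length-H vector across the columns of an n x H matrix
rowBroadcast <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

linearFwd <- function(x, W, b) {
  y <- x %*% W
  # add the bias via column-major recycling of rep(b, each = n)
  y + rep(b, each = nrow(x))
}

linearBwd <- function(dy, x, W) {
  list(dx = tcrossprod(dy, W), dW = crossprod(x, dy),
       db = .colSums(dy, nrow(dy), ncol(dy)))
}

# row-wise layer normalization with learned gain/bias
layerNormFwd <- function(x, g, beta, eps = 1e-5) {
  n <- nrow(x); H <- ncol(x)
  mu <- .rowMeans(x, n, H)
  xc <- x - mu
  v <- .rowMeans(xc * xc, n, H)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = xhat * rep(g, each = n) + rep(beta, each = n),
       xhat = xhat, inv = inv)
}

layerNormBwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  n <- nrow(dy); H <- ncol(dy)
  dg <- .colSums(dy * xhat, n, H)
  dbeta <- .colSums(dy, n, H)
  dxhat <- dy * rep(g, each = n)
  dx <- (dxhat - .rowMeans(dxhat, n, H) -
         xhat * .rowMeans(dxhat * xhat, n, H)) * cache$inv
  list(dx = dx, dg = dg, dbeta = dbeta)
}

reluFwd <- function(x) x * (x > 0)
reluBwd <- function(dy, x) dy * (x > 0)

rowMax <- function(x) {
  m <- x[, 1L]
  for (j in seq_len(ncol(x))[-1L]) m <- pmax.int(m, x[, j])
  m
}

softmaxRows <- function(x) {
  e <- exp(x - rowMax(x))
  e / .rowSums(e, nrow(e), ncol(e))
}

# backward through row-wise softmax: p = softmax(x), given dL/dp
softmaxRowsBwd <- function(dp, p) {
  p * (dp - .rowSums(dp * p, nrow(p), ncol(p)))
}

# clamp with an indicator for gradient gating
clampFwd <- function(x, lo, hi) {
  y <- pmin(pmax(x, lo), hi)
  list(y = y, ind = (x > lo & x < hi) * 1)
}

# numerically stable row-wise log-sum-exp
logSumExpRows <- function(x) {
  m <- rowMax(x)
  m + log(.rowSums(exp(x - m), nrow(x), ncol(x)))
}

# Kaiming-style initialisation of the flat parameter list
initMatrix <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

# Adam with decoupled-from-nothing L2 weight decay folded into the gradient
# (torch Adam convention), lr 1e-3 / wd 1e-6 defaults.
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = lapply(params, function(p) 0L))
}

# the step counter is per parameter so that extra updates of one network
# (the adversarial classifier) leave the bias correction of all others
# untouched
adamStep <- function(params, grads, state, lr = 1e-3, weight_decay = 1e-6,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    t <- state$t[[nm]] + 1L
    state$t[[nm]] <- t
    g <- grads[[nm]] + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / (1 - beta1^t)) /
        (sqrt(state$v[[nm]] / (1 - beta2^t)) + eps)
  }
  list(params = params, state = state)
}
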
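# Minimal dense neural-network primitives: activations, fan-in initialization,
# Adam, and the MLP classification head shared by all model variants.
# Parameters live in flat named lists of matrices/vectors; gradients mirror
# that layout. All randomness is drawn from R's RNG so a single seed fixes
# initialization, shuffling and dropout.

relu <- function(x) x * (x > 0)

# add a bias row-vector to every row of a matrix (column-major recycling)
addvec <- function(M, b) M + rep(b, each = nrow(M))

sigmoid <- function(x) 1 / (1 + exp(-x))

# shifted softplus: ln(0.5 e^x + 0.5), zero at x = 0 (SchNet nonlinearity)
ssp <- function(x) pmax(x, 0) + log1p(exp(-abs(x))) - log(2)

ssp_grad <- function(x) sigmoid(x)

# uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_mat <- function(nr, nc) {
  s <- 1 / sqrt(nr)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---- MLP head -------------------------------------------------------------

mlp_init_params <- function(d_in, hidden) {
  params <- list()
  d_prev <- d_in
  for (m in seq_along(hidden)) {
    params[[paste0("mlp.W", m)]] <- init_mat(d_prev, hidden[m])
    params[[paste0("mlp.b", m)]] <- numeric(hidden[m])
    d_prev <- hidden[m]
  }
  params[["mlp.Wout"]] <- init_mat(d_prev, 1)
  params[["mlp.bout"]] <- 0
  params
}

# Forward pass of the MLP head: hidden ReLU layers with (inverted) dropout
# during training, sigmoid output. Returns scores and a cache for backprop.
mlp_forward <- function(Z, params, hidden, dropout = 0, training = FALSE) {
  A <- Z
  cache <- list(A = list(A), Zpre = list(), mask = list())
  for (m in seq_along(hidden)) {
    P <- addvec(A %*% params[[paste0("mlp.W", m)]],
                params[[paste0("mlp.b", m)]])
    A <- relu(P)
    if (training && dropout > 0) {
      mask <- matrix(stats::runif(length(A)) >= dropout, nrow(A), ncol(A)) /
        (1 - dropout)
      A <- A * mask
      cache$mask[[m]] <- mask
    }
    cache$Zpre[[m]] <- P
    cache$A[[m + 1]] <- A
  }
  logit <- drop(A %*% params[["mlp.Wout"]]) + params[["mlp.bout"]]
  p <- sigmoid(logit)
  cache$logit <- logit
  list(p = p, cache = cache)
}

# Backward pass given dL/dlogit; returns gradients and dL/dZ (input).
mlp_backward <- function(dlogit, cache, params, hidden, dropout = 0,
                         training = FALSE) {
  grads <- list()
  M <- length(hidden)
  A_last <- cache$A[[M + 1]]
  grads[["mlp.Wout"]] <- crossprod(A_last, dlogit)
  grads[["mlp.bout"]] <- sum(dlogit)
  dA <- tcrossprod(dlogit, params[["mlp.Wout"]])
  for (m in rev(seq_len(M))) {
    if (training && dropout > 0) dA <- dA * cache$mask[[m]]
    dP <- dA * (cache$Zpre[[m]] > 0)
    grads[[paste0("mlp.W", m)]] <- crossprod(cache$A[[m]], dP)
    grads[[paste0("mlp.b", m)]] <- colSums(dP)
    dA <- tcrossprod(dP, params[[paste0("mlp.W", m)]])
  }
  list(grads = grads, dZ = dA)
}

# run code with a deterministic RNG substream, restoring the caller's state
with_preserved_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
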
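# Small dense-network primitives shared by the representation learner and the
# conditioning networks of the flows.  Kept internal: the public surface of the
# package speaks in cohorts, features and fitted models, not layers.

elu <- function(x) ifelse(x > 0, x, expm1(x))
elu_grad <- function(x) ifelse(x > 0, 1, exp(x))

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# log(cosh(x)) without overflow
logcosh <- function(x) {
  ax <- abs(x)
  ax + log1p(exp(-2 * ax)) - log(2)
}

# log(|sinh(x)|) without overflow; x must be non-zero where used
logabs_sinh <- function(x) {
  ax <- abs(x)
  ax + log1p(-exp(-2 * ax)) - log(2)
}

# log(exp(a) + exp(b)) elementwise
lse2 <- function(a, b) {
  m <- pmax(a, b)
  m + log1p(exp(-abs(a - b)))
}

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

# Adam optimizer over a flat list of numeric arrays.  State is carried in a
# closure-free list so models stay serialisable.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  for (k in seq_along(params)) {
    g <- grads[[k]]
    if (weight_decay > 0) g <- g + weight_decay * params[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / (1 - beta1^t)
    vhat <- state$v[[k]] / (1 - beta2^t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Stratified minibatch index generator: every batch carries both treatment
# arms (required whenever the balancing penalty is active).
stratified_batches <- function(a, batch_size) {
  i0 <- sample(which(a == 0L))
  i1 <- sample(which(a == 1L))
  n <- length(a)
  n_batches <- max(1L, ceiling(n / batch_size))
  b0 <- split(i0, cut(seq_along(i0), n_batches, labels = FALSE))
  b1 <- split(i1, cut(seq_along(i1), n_batches, labels = FALSE))
  lapply(seq_len(n_batches), function(b) {
    c(b0[[min(b, length(b0))]], b1[[min(b, length(b1))]])
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
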
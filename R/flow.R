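# Conditional normalizing flows over a scalar variable.
#
# The outcome of interest is binary; it enters the flow after uniform
# dequantization and a logit link, so both the outcome flow and the
# hidden-confounder flow act on a 1-D continuous variable.  Each layer is a
# conditional affine map z -> a(c) + exp(s(c)) * z, with (a, s) produced by a
# small conditioning network from the conditioning vector c (representation
# plus arm for the outcome flow; representation alone for the adjustment
# flow), followed by the learnable invertible nonlinearity
#     g(u) = asinh(gamma * sinh(u)),   gamma > 0,
# which is the exact identity at gamma = 1.  Zero-initialised conditioning
# outputs and gamma = 1 make a freshly created flow the identity map with zero
# log-determinant, which is what the staged training relies on: the adjustment
# flow starts as identity so the composed likelihood initially coincides with
# the outcome-flow likelihood.

flow_new <- function(n_layers, cond_dim, hidden = 16L) {
  layers <- lapply(seq_len(n_layers), function(k) {
    list(
      W1 = he_init(cond_dim, hidden),
      b1 = numeric(hidden),
      W2 = matrix(0, hidden, 2),   # zero: (a, s) = b2 = 0 at init
      b2 = numeric(2),
      lgamma = 0                   # gamma = exp(lgamma) = 1 at init
    )
  })
  structure(list(layers = layers, cond_dim = cond_dim, hidden = hidden),
            class = "flowcfr_flow")
}

flow_params <- function(flow) {
  unlist(lapply(flow$layers, function(l) l[c("W1", "b1", "W2", "b2", "lgamma")]),
         recursive = FALSE)
}

flow_set_params <- function(flow, params) {
  nms <- c("W1", "b1", "W2", "b2", "lgamma")
  for (k in seq_along(flow$layers)) {
    flow$layers[[k]][nms] <- params[(k - 1L) * 5L + seq_len(5L)]
  }
  flow
}

# Conditioning network of one layer: c (n x d) -> a, s (n-vectors).
cond_net <- function(layer, cond) {
  pre <- sweep(cond %*% layer$W1, 2, layer$b1, "+")
  H <- elu(pre)
  AS <- sweep(H %*% layer$W2, 2, layer$b2, "+")
  list(a = AS[, 1], s = AS[, 2], H = H, pre = pre)
}

# asinh(gamma * sinh(u)) and its inverse, evaluated in log-space for large
# |u| where sinh would overflow: there asinh(gamma sinh u) = sign(u)(|u| +
# log gamma) up to an error below exp(-2|u|), so the two branches agree to
# machine precision at the switch point and the pair stays exactly
# self-inverse in the large regime.
sinh_warp <- function(u, lgamma) {
  big <- abs(u) > 30
  out <- u
  out[big] <- sign(u[big]) * (abs(u[big]) + lgamma)
  out[!big] <- asinh(exp(lgamma) * sinh(u[!big]))
  out
}

sinh_warp_inv <- function(t, lgamma) {
  big <- abs(t) > 30
  out <- t
  out[big] <- sign(t[big]) * (abs(t[big]) - lgamma)
  out[!big] <- asinh(sinh(t[!big]) / exp(lgamma))
  out
}

#' Forward pass of a conditional flow
#'
#' Maps latent values through the stack of invertible conditional layers and
#' accumulates the log-determinant of the Jacobian.
#'
#' @param flow A flow created by the model constructors (class
#'   `flowcfr_flow`).
#' @param z Numeric vector of latent values.
#' @param cond Numeric matrix of conditioning vectors, one row per element of
#'   `z` (a single row is recycled).
#' @return A list with `value` (transformed vector) and `log_det`
#'   (per-element log-determinant of the forward Jacobian).
#' @export
flow_forward <- function(flow, z, cond) {
  cond <- cond_matrix(cond, length(z), flow$cond_dim)
  if (!all(is.finite(z))) stop("flow_forward: non-finite latent input")
  log_det <- numeric(length(z))
  for (k in seq_along(flow$layers)) {
    l <- flow$layers[[k]]
    cn <- cond_net(l, cond)
    u <- cn$a + exp(cn$s) * z
    if (l$lgamma == 0) {            # gamma = 1: nonlinearity is the exact identity
      z <- u
      ld <- cn$s
    } else {
      z <- sinh_warp(u, l$lgamma)
      ld <- cn$s + l$lgamma + logcosh(u) - half_log1p_g2sinh2(u, l$lgamma)
    }
    if (!all(is.finite(z)) || !all(is.finite(ld))) {
      stop(sprintf("flow_forward: non-finite value at layer %d", k))
    }
    log_det <- log_det + ld
  }
  list(value = z, log_det = log_det)
}

#' Inverse pass of a conditional flow
#'
#' Exact inverse of [flow_forward()]; the returned `log_det` is the
#' log-determinant of the inverse Jacobian, i.e. the negative of the forward
#' one at corresponding points.
#'
#' @inheritParams flow_forward
#' @param y Numeric vector in the output space of the flow.
#' @return A list with `value` (latent vector) and `log_det`.
#' @export
flow_inverse <- function(flow, y, cond) {
  cond <- cond_matrix(cond, length(y), flow$cond_dim)
  if (!all(is.finite(y))) stop("flow_inverse: non-finite input")
  log_det <- numeric(length(y))
  for (k in rev(seq_along(flow$layers))) {
    l <- flow$layers[[k]]
    cn <- cond_net(l, cond)
    t <- y
    if (l$lgamma == 0) {
      u <- t
      ld <- -cn$s
    } else {
      u <- sinh_warp_inv(t, l$lgamma)
      ld <- -cn$s + logcosh(t) - half_log_g2_plus_sinh2(t, l$lgamma)
    }
    y <- (u - cn$a) * exp(-cn$s)
    if (!all(is.finite(y)) || !all(is.finite(ld))) {
      stop(sprintf("flow_inverse: non-finite value at layer %d", k))
    }
    log_det <- log_det + ld
  }
  list(value = y, log_det = log_det)
}

cond_matrix <- function(cond, n, d) {
  if (is.vector(cond)) cond <- matrix(cond, nrow = 1)
  if (nrow(cond) == 1L && n > 1L) cond <- cond[rep(1L, n), , drop = FALSE]
  if (nrow(cond) != n) stop("conditioning rows do not match input length")
  if (ncol(cond) != d) stop("conditioning dimension mismatch")
  cond
}

# 0.5 * log(1 + gamma^2 sinh(u)^2), overflow-safe
half_log1p_g2sinh2 <- function(u, lgamma) {
  out <- numeric(length(u))
  small <- abs(u) < 1
  if (any(small)) {
    out[small] <- 0.5 * log1p(exp(2 * lgamma) * sinh(u[small])^2)
  }
  if (any(!small)) {
    t <- lgamma + logabs_sinh(u[!small])
    out[!small] <- t + 0.5 * log1p(exp(-2 * t))
  }
  out
}

# 0.5 * log(gamma^2 + sinh(t)^2), overflow-safe
half_log_g2_plus_sinh2 <- function(t, lgamma) {
  out <- numeric(length(t))
  small <- abs(t) < 1
  if (any(small)) {
    out[small] <- 0.5 * log(exp(2 * lgamma) + sinh(t[small])^2)
  }
  if (any(!small)) {
    out[!small] <- 0.5 * lse2(rep(2 * lgamma, sum(!small)),
                              2 * logabs_sinh(t[!small]))
  }
  out
}

# Negative log-likelihood of observations under the flow-transformed standard
# normal, with analytic gradients for all flow parameters.  `y` lives in the
# flow's output space; `weight_base` multiplies the base-density term (always
# 1 here, kept explicit for clarity of the change-of-variables formula).
flow_nll <- function(flow, y, cond, grad = FALSE) {
  cond <- cond_matrix(cond, length(y), flow$cond_dim)
  n <- length(y)
  K <- length(flow$layers)
  caches <- vector("list", K)
  log_det <- numeric(n)
  z <- y
  for (k in rev(seq_len(K))) {
    l <- flow$layers[[k]]
    cn <- cond_net(l, cond)
    g <- exp(l$lgamma)
    t_in <- z
    if (l$lgamma == 0) {
      u <- t_in
      ld <- -cn$s
    } else {
      u <- sinh_warp_inv(t_in, l$lgamma)
      ld <- -cn$s + logcosh(t_in) - half_log_g2_plus_sinh2(t_in, l$lgamma)
    }
    z_out <- (u - cn$a) * exp(-cn$s)
    caches[[k]] <- list(t = t_in, u = u, z_out = z_out, cn = cn, g = g)
    log_det <- log_det + ld
    z <- z_out
  }
  z0 <- z
  nll_i <- 0.5 * z0^2 + 0.5 * log(2 * pi) - log_det
  out <- list(nll = mean(nll_i), nll_i = nll_i, z = z0, log_det = log_det)
  if (!grad) return(out)

  grads <- stats::setNames(
    rep(list(NULL), 5L * K),
    paste0(rep(c("W1", "b1", "W2", "b2", "lgamma"), K), ".",
           rep(seq_len(K), each = 5))
  )
  gz <- z0 / n                      # d mean-NLL / d z0
  for (k in seq_len(K)) {
    cc <- caches[[k]]
    l <- flow$layers[[k]]
    g <- cc$g
    t <- cc$t
    sh <- sinh(t); ch <- cosh(t)
    g2s2 <- g^2 + sh^2
    es <- exp(-cc$cn$s)
    ga <- gz * (-es)                                   # dL/da (vector)
    gs <- gz * (-cc$z_out) + 1 / n                     # dL/ds
    du_dg <- -sh / (g * sqrt(g2s2))
    dl_dg <- -g / g2s2               # d(per-layer log-det)/d gamma
    ggam <- sum(gz * es * du_dg) - sum(dl_dg) / n
    dl_dt <- tanh(t) - sh * ch / g2s2
    gt <- gz * es * (ch / sqrt(g2s2)) - (1 / n) * dl_dt

    # backprop (a, s) through the conditioning net
    dAS <- cbind(ga, gs)
    gW2 <- t(cc$cn$H) %*% dAS
    gb2 <- colSums(dAS)
    dH <- dAS %*% t(l$W2) * elu_grad(cc$cn$pre)
    gW1 <- t(cond) %*% dH
    gb1 <- colSums(dH)

    grads[[paste0("W1.", k)]] <- gW1
    grads[[paste0("b1.", k)]] <- gb1
    grads[[paste0("W2.", k)]] <- gW2
    grads[[paste0("b2.", k)]] <- gb2
    grads[[paste0("lgamma.", k)]] <- ggam * g   # chain rule to lgamma
    gz <- gt
  }
  out$grads <- grads
  out
}
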
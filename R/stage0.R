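# Stage 0: balanced representation learning.
#
# A staleness gate shrinks each channel's feature block towards the
# (standardized) population mean as its time-since-last-measurement grows,
# with a learnable per-channel decay; the gated features pass through a
# feedforward encoder producing the representation phi; two arm-specific
# logistic heads predict the factual outcome.  The loss is the factual binary
# cross-entropy plus lambda times the exact Wasserstein-1 distance between the
# per-arm representation batches, which pushes the encoder towards
# arm-balanced representations.

stage0_new <- function(n_features, n_channels, hidden = 32L, rep_dim = 8L) {
  list(
    gate_w = rep(-2, n_channels),          # softplus(-2) ~ 0.13: slow decay at init
    W1 = he_init(n_features, hidden), b1 = numeric(hidden),
    W2 = he_init(hidden, rep_dim) * 0.5, b2 = numeric(rep_dim),
    head_niv = list(w = numeric(rep_dim), b = 0),
    head_hfnc = list(w = numeric(rep_dim), b = 0),
    n_channels = n_channels, hidden = hidden, rep_dim = rep_dim
  )
}

#' Staleness gate over channel feature blocks
#'
#' Multiplies each channel's (current, baseline, slope) features by
#' `exp(-softplus(w_c) * tslm_c)`, a learnable monotone-nonincreasing function
#' of the channel's time-since-last-measurement with value 1 at `tslm = 0`.
#' The TSLM features themselves and the static block pass through unchanged.
#'
#' @param features A `flowcfr_features` object.
#' @param gate_w Per-channel gate parameters (decay is `softplus(gate_w)`);
#'   defaults to a slow uniform decay.
#' @return The gated feature matrix.
#' @export
tslm_gate <- function(features, gate_w = rep(-2, length(features$channels))) {
  if (any(features$tslm < 0, na.rm = TRUE)) stop("negative tslm")
  gate_matrix(features, gate_w)$xg
}

gate_matrix <- function(features, gate_w) {
  X <- features$x
  C <- length(features$channels)
  if (C == 0L) return(list(xg = X, G = matrix(1, nrow(X), 0)))
  G <- exp(-sweep(features$tslm, 2, softplus(gate_w), "*"))   # n x C
  Xg <- X
  for (blk in 0:2) {                      # raw, baseline, delta blocks
    cols <- blk * C + seq_len(C)
    Xg[, cols] <- X[, cols] * G
  }
  list(xg = Xg, G = G)
}

stage0_forward <- function(params, features) {
  gm <- gate_matrix(features, params$gate_w)
  pre1 <- sweep(gm$xg %*% params$W1, 2, params$b1, "+")
  H <- elu(pre1)
  phi <- sweep(H %*% params$W2, 2, params$b2, "+")
  logit0 <- drop(phi %*% params$head_niv$w) + params$head_niv$b
  logit1 <- drop(phi %*% params$head_hfnc$w) + params$head_hfnc$b
  list(phi = phi, p0 = plogis(logit0), p1 = plogis(logit1),
       H = H, pre1 = pre1, gm = gm)
}

#' Encode features into the balanced representation
#'
#' Deterministic map from features to the representation phi of a trained (or
#' freshly initialised) Stage 0.
#'
#' @param params Stage 0 parameter list (from a fitted `repflow_model`, field
#'   `stage0`, or [tslm_gate()]-compatible initialisation).
#' @param features A `flowcfr_features` object.
#' @return Numeric matrix, one representation row per encounter.
#' @export
encode <- function(params, features) {
  if (ncol(features$x) != nrow(params$W1)) {
    stop("encode: feature dimension does not match the encoder")
  }
  stage0_forward(params, features)$phi
}

#' Stage 0 loss: factual cross-entropy plus balancing penalty
#'
#' Binary cross-entropy of the assigned arm's head prediction plus `lambda`
#' times the exact Wasserstein-1 distance between the per-arm representation
#' batches.
#'
#' @param params Stage 0 parameters.
#' @param features `flowcfr_features` for the batch.
#' @param a Treatment vector (0 = NIV, 1 = HFNC).
#' @param y Outcome vector (0/1).
#' @param lambda Balancing weight (>= 0).
#' @return Scalar loss (see `attr(, "parts")` for the two components).
#' @export
stage0_loss <- function(params, features, a, y, lambda = 1) {
  res <- stage0_loss_grad(params, features, a, y, lambda, grad = FALSE)
  out <- res$loss
  attr(out, "parts") <- c(bce = res$bce, ipm = res$ipm)
  out
}

stage0_loss_grad <- function(params, features, a, y, lambda, grad = TRUE) {
  n <- length(y)
  fw <- stage0_forward(params, features)
  p_fact <- ifelse(a == 1L, fw$p1, fw$p0)
  eps <- 1e-12
  bce <- -mean(y * log(p_fact + eps) + (1 - y) * log(1 - p_fact + eps))

  ipm <- 0
  plan <- NULL
  i0 <- which(a == 0L); i1 <- which(a == 1L)
  if (lambda > 0) {
    if (length(i0) == 0L || length(i1) == 0L) {
      stop("stage0_loss: both arms required in a batch when lambda > 0")
    }
    ph0 <- fw$phi[i0, , drop = FALSE]
    ph1 <- fw$phi[i1, , drop = FALSE]
    ot <- ot_w1(ph0, ph1)
    ipm <- ot$cost
    plan <- ot$cells
  }
  loss <- bce + lambda * ipm
  if (!grad) return(list(loss = loss, bce = bce, ipm = ipm))

  ## ---- backward ----
  dlogit <- (p_fact - y) / n
  dphi <- matrix(0, n, params$rep_dim)
  g_h0w <- numeric(params$rep_dim); g_h0b <- 0
  g_h1w <- numeric(params$rep_dim); g_h1b <- 0
  r0 <- a == 0L; r1 <- a == 1L
  if (any(r0)) {
    dphi[r0, ] <- outer(dlogit[r0], params$head_niv$w)
    g_h0w <- drop(t(fw$phi[r0, , drop = FALSE]) %*% dlogit[r0])
    g_h0b <- sum(dlogit[r0])
  }
  if (any(r1)) {
    dphi[r1, ] <- outer(dlogit[r1], params$head_hfnc$w)
    g_h1w <- drop(t(fw$phi[r1, , drop = FALSE]) %*% dlogit[r1])
    g_h1b <- sum(dlogit[r1])
  }

  if (lambda > 0 && !is.null(plan)) {
    # envelope gradient: optimal plan fixed, differentiate the transport cost
    ph0 <- fw$phi[i0, , drop = FALSE]
    ph1 <- fw$phi[i1, , drop = FALSE]
    for (k in seq_len(nrow(plan))) {
      ii <- plan$i[k]; jj <- plan$j[k]; m <- plan$mass[k]
      diff <- ph0[ii, ] - ph1[jj, ]
      d <- sqrt(sum(diff^2))
      if (d > 1e-12) {
        gvec <- lambda * m * diff / d
        dphi[i0[ii], ] <- dphi[i0[ii], ] + gvec
        dphi[i1[jj], ] <- dphi[i1[jj], ] - gvec
      }
    }
  }

  dH <- dphi %*% t(params$W2)
  gW2 <- t(fw$H) %*% dphi
  gb2 <- colSums(dphi)
  dpre1 <- dH * elu_grad(fw$pre1)
  gW1 <- t(fw$gm$xg) %*% dpre1
  gb1 <- colSums(dpre1)

  C <- params$n_channels
  g_gate <- numeric(C)
  if (C > 0L) {
    dXg <- dpre1 %*% t(params$W1)
    X <- features$x
    G <- fw$gm$G
    sg <- plogis(params$gate_w)    # d softplus
    for (c in seq_len(C)) {
      cols <- c(c, C + c, 2L * C + c)
      dG_c <- rowSums(dXg[, cols, drop = FALSE] * X[, cols, drop = FALSE])
      g_gate[c] <- sum(dG_c * G[, c] * (-features$tslm[, c])) * sg[c]
    }
  }

  list(loss = loss, bce = bce, ipm = ipm,
       grads = list(gate_w = g_gate, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    head_niv.w = g_h0w, head_niv.b = g_h0b,
                    head_hfnc.w = g_h1w, head_hfnc.b = g_h1b))
}

stage0_get_params <- function(p) {
  list(gate_w = p$gate_w, W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2,
       head_niv.w = p$head_niv$w, head_niv.b = p$head_niv$b,
       head_hfnc.w = p$head_hfnc$w, head_hfnc.b = p$head_hfnc$b)
}

stage0_set_params <- function(p, flat) {
  p$gate_w <- flat$gate_w; p$W1 <- flat$W1; p$b1 <- flat$b1
  p$W2 <- flat$W2; p$b2 <- flat$b2
  p$head_niv <- list(w = flat$head_niv.w, b = flat$head_niv.b)
  p$head_hfnc <- list(w = flat$head_hfnc.w, b = flat$head_hfnc.b)
  p
}

# Validation loss for early stopping: factual cross-entropy plus the
# balancing penalty, the latter on at most `cap` representations per arm
# (the exact solver is cubic in the group size; a capped subset tracks the
# same signal at a fraction of the cost).
stage0_val_loss <- function(params, features, a, y, lambda, cap = 64L) {
  fw <- stage0_forward(params, features)
  p_fact <- ifelse(a == 1L, fw$p1, fw$p0)
  eps <- 1e-12
  bce <- -mean(y * log(p_fact + eps) + (1 - y) * log(1 - p_fact + eps))
  ipm <- 0
  if (lambda > 0) {
    i0 <- which(a == 0L); i1 <- which(a == 1L)
    if (length(i0) == 0L || length(i1) == 0L) {
      stop("validation split lacks a treatment arm")
    }
    ipm <- ipm_distance(fw$phi[head(i0, cap), , drop = FALSE],
                        fw$phi[head(i1, cap), , drop = FALSE])
  }
  bce + lambda * ipm
}

train_stage0 <- function(features, a, y, config, val_idx) {
  n <- nrow(features$x)
  params <- stage0_new(ncol(features$x), length(features$channels),
                       hidden = config$hidden, rep_dim = config$rep_dim)
  flat <- stage0_get_params(params)
  opt <- adam_init(flat)
  tr_idx <- setdiff(seq_len(n), val_idx)
  ftr <- features_subset(features, tr_idx)
  fval <- features_subset(features, val_idx)

  best <- Inf; best_flat <- flat; wait <- 0L
  history <- numeric(0)
  for (epoch in seq_len(config$epochs)) {
    batches <- stratified_batches(a[tr_idx], config$batch_size)
    for (b in batches) {
      idx <- tr_idx[b]
      res <- stage0_loss_grad(stage0_set_params(params, flat),
                              features_subset(features, idx),
                              a[idx], y[idx], config$lambda)
      step <- adam_step(flat, res$grads, opt, lr = config$lr,
                        weight_decay = config$weight_decay)
      flat <- step$params; opt <- step$state
    }
    vloss <- stage0_val_loss(stage0_set_params(params, flat), fval,
                             a[val_idx], y[val_idx], config$lambda)
    history <- c(history, vloss)
    if (vloss < best - 1e-6) {
      best <- vloss; best_flat <- flat; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  list(params = stage0_set_params(params, best_flat), val_history = history)
}
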
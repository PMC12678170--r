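# Staged training of the full counterfactual model:
#   stage 0 (balanced representation + factual heads)  ->  frozen
#   stage 1 (conditional flow over the dequantized outcome given phi, arm)
#   stage 2 (conditional flow re-modeling the latent given phi alone)
# Each stage is optimised with Adam and early stopping on an internal
# validation split; earlier stages are frozen while later stages train.

#' Default model configuration
#'
#' @param hidden Encoder hidden width.
#' @param rep_dim Representation dimension.
#' @param lambda Balancing (Wasserstein) weight in the Stage 0 loss.  The
#'   default is deliberately mild: strong balancing can strip covariates that
#'   drive both treatment selection and effect heterogeneity out of the
#'   representation (see the methods vignette).
#' @param flow_depth Number of invertible layers per flow.
#' @param flow_hidden Hidden width of each flow's conditioning network.
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty applied through the optimiser.
#' @param batch_size Minibatch size.
#' @param epochs Maximum epochs per stage.
#' @param patience Early-stopping patience (epochs) on validation loss.
#' @param val_frac Internal validation fraction (stratified by arm x outcome).
#' @param n_mc Default Monte-Carlo samples for counterfactual inference.
#' @return A list of class `flowcfr_config`.
#' @export
repflow_config <- function(hidden = 32L, rep_dim = 8L, lambda = 0.01,
                           flow_depth = 3L, flow_hidden = 16L, lr = 5e-3,
                           weight_decay = 1e-5, batch_size = 128L,
                           epochs = 60L, patience = 10L, val_frac = 0.2,
                           n_mc = 128L) {
  cfg <- list(hidden = as.integer(hidden), rep_dim = as.integer(rep_dim),
              lambda = lambda, flow_depth = as.integer(flow_depth),
              flow_hidden = as.integer(flow_hidden), lr = lr,
              weight_decay = weight_decay, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), patience = as.integer(patience),
              val_frac = val_frac, n_mc = as.integer(n_mc))
  if (cfg$lambda < 0) stop("lambda must be >= 0")
  structure(cfg, class = "flowcfr_config")
}

# stratified (arm x outcome) validation indices
stratified_val_split <- function(a, y, val_frac) {
  cells <- interaction(a, y, drop = TRUE)
  unlist(lapply(split(seq_along(a), cells), function(idx) {
    k <- max(1L, round(length(idx) * val_frac))
    sample(idx, k)
  }), use.names = FALSE)
}

# uniform dequantization of a binary outcome: y' = logit((y + e)/2), e ~ U(0,1)
dequantize <- function(y, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- runif(length(y))
  pmin(pmax(qlogis((y + e) / 2), -15), 15)
}

#' Train the three-stage counterfactual model
#'
#' @param features A `flowcfr_features` object.
#' @param a Treatment vector (0 = NIV, 1 = HFNC).
#' @param y Binary outcome vector (1 = IMV).
#' @param config A [repflow_config()].
#' @param seed Integer seed controlling the split, batching, initialisation
#'   and dequantization.
#' @return A fitted `repflow_model`: Stage 0 parameters, the two flows, the
#'   configuration, seeds and per-stage validation histories.
#' @export
repflow_train <- function(features, a, y, config = repflow_config(),
                          seed = 1L) {
  stopifnot(inherits(features, "flowcfr_features"))
  a <- as.integer(a); y <- as.integer(y)
  if (length(unique(a)) < 2L) stop("both treatment arms required")
  if (length(unique(y)) < 2L) stop("both outcome classes required")
  set.seed(seed)
  val_idx <- stratified_val_split(a, y, config$val_frac)
  if (length(unique(y[val_idx])) < 2L || length(unique(a[val_idx])) < 2L) {
    stop("validation split lacks an arm or outcome class")
  }

  s0 <- train_stage0(features, a, y, config, val_idx)
  phi <- stage0_forward(s0$params, features)$phi

  yq <- dequantize(y, seed = seed + 1L)
  cond1 <- cbind(phi, arm = a)
  flow1 <- flow_new(config$flow_depth, ncol(cond1), config$flow_hidden)
  f1 <- train_flow(flow1, yq, cond1, config, val_idx, seed = seed + 2L)

  # stage 2 trains on the stage-1 latent residuals, conditioned on phi only
  v <- flow_inverse(f1$flow, yq, cond1)$value
  flow2 <- flow_new(config$flow_depth, ncol(phi), config$flow_hidden)
  f2 <- train_flow(flow2, v, phi, config, val_idx, seed = seed + 3L)

  structure(
    list(stage0 = s0$params, flow1 = f1$flow, flow2 = f2$flow,
         config = config, seed = seed,
         history = list(stage0 = s0$val_history, stage1 = f1$val_history,
                        stage2 = f2$val_history),
         scaler = features$scaler, channels = features$channels,
         statics = features$statics, n_train = nrow(features$x)),
    class = "repflow_model"
  )
}

train_flow <- function(flow, target, cond, config, val_idx, seed) {
  set.seed(seed)
  n <- length(target)
  tr_idx <- setdiff(seq_len(n), val_idx)
  params <- flow_params(flow)
  opt <- adam_init(params)
  best <- Inf; best_params <- params; wait <- 0L
  history <- numeric(0)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (b in batches) {
      fl <- flow_set_params(flow, params)
      res <- flow_nll(fl, target[b], cond[b, , drop = FALSE], grad = TRUE)
      step <- adam_step(params, res$grads, opt, lr = config$lr,
                        weight_decay = config$weight_decay)
      params <- step$params; opt <- step$state
    }
    vnll <- flow_nll(flow_set_params(flow, params), target[val_idx],
                     cond[val_idx, , drop = FALSE])$nll
    history <- c(history, vnll)
    if (vnll < best - 1e-6) {
      best <- vnll; best_params <- params; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  list(flow = flow_set_params(flow, best_params), val_history = history)
}

#' Stage 1 negative log-likelihood of a batch
#'
#' Mean negative log-likelihood of dequantized outcomes under the
#' change-of-variables density of the outcome flow conditioned on
#' (representation, arm).
#'
#' @param model A fitted `repflow_model`.
#' @param features,a,y Batch (outcome in {0,1}).
#' @param seed Seed for the dequantization draw.
#' @return Scalar mean NLL.
#' @export
stage1_nll <- function(model, features, a, y, seed = 1L) {
  check_binary_outcome(y)
  phi <- stage0_forward(model$stage0, features)$phi
  yq <- dequantize(y, seed = seed)
  flow_nll(model$flow1, yq, cbind(phi, arm = as.integer(a)))$nll
}

#' Stage 2 negative log-likelihood of a batch
#'
#' Mean negative log-likelihood under the composed transform (adjustment flow
#' then outcome flow).  With the adjustment flow at its identity
#' initialisation this equals [stage1_nll()] exactly.
#'
#' @inheritParams stage1_nll
#' @return Scalar mean NLL.
#' @export
stage2_nll <- function(model, features, a, y, seed = 1L) {
  check_binary_outcome(y)
  phi <- stage0_forward(model$stage0, features)$phi
  yq <- dequantize(y, seed = seed)
  inv1 <- flow_inverse(model$flow1, yq, cbind(phi, arm = as.integer(a)))
  inv2 <- flow_inverse(model$flow2, inv1$value, phi)
  mean(0.5 * inv2$value^2 + 0.5 * log(2 * pi) - inv1$log_det - inv2$log_det)
}

check_binary_outcome <- function(y) {
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1)")
}

#' Fine-tune a trained model on a new site
#'
#' Draws a stratified (arm x outcome) `fraction` subset with a logged seed and
#' re-optimises all three stages from the checkpoint, reusing the original
#' hyperparameters.
#'
#' @param model A fitted `repflow_model`.
#' @param features,a,y New-site data.
#' @param fraction Stratified subset fraction in (0, 1].
#' @param seed Seed for subset membership and training.
#' @return A fitted `repflow_model` with a `finetune` field recording the
#'   subset ids and seed.
#' @export
repflow_finetune <- function(model, features, a, y, fraction = 0.25,
                             seed = 1L) {
  a <- as.integer(a); y <- as.integer(y)
  set.seed(seed)
  cells <- interaction(a, y, drop = TRUE)
  sub <- sort(unlist(lapply(split(seq_along(a), cells), function(idx) {
    sample(idx, max(1L, round(length(idx) * fraction)))
  }), use.names = FALSE))
  if (length(sub) < model$config$batch_size / 4) {
    stop("fine-tuning subset smaller than a quarter batch")
  }
  fs <- features_subset(features, sub)
  as <- a[sub]; ys <- y[sub]
  val_idx <- stratified_val_split(as, ys, model$config$val_frac)

  cfg <- model$config
  s0 <- continue_stage0(model$stage0, fs, as, ys, cfg, val_idx)
  phi <- stage0_forward(s0$params, fs)$phi
  yq <- dequantize(ys, seed = seed + 1L)
  cond1 <- cbind(phi, arm = as)
  f1 <- train_flow(model$flow1, yq, cond1, cfg, val_idx, seed = seed + 2L)
  v <- flow_inverse(f1$flow, yq, cond1)$value
  f2 <- train_flow(model$flow2, v, phi, cfg, val_idx, seed = seed + 3L)

  out <- model
  out$stage0 <- s0$params; out$flow1 <- f1$flow; out$flow2 <- f2$flow
  out$history <- list(stage0 = s0$val_history, stage1 = f1$val_history,
                      stage2 = f2$val_history)
  out$finetune <- list(subset_ids = fs$encounter_id, fraction = fraction,
                       seed = seed)
  out
}

continue_stage0 <- function(params, features, a, y, config, val_idx) {
  flat <- stage0_get_params(params)
  opt <- adam_init(flat)
  n <- nrow(features$x)
  tr_idx <- setdiff(seq_len(n), val_idx)
  best <- Inf; best_flat <- flat; wait <- 0L; history <- numeric(0)
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
    vloss <- stage0_val_loss(stage0_set_params(params, flat),
                             features_subset(features, val_idx),
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

#' Random hyperparameter search maximising internal-validation AUC
#'
#' Samples `budget` configurations uniformly from a finite space, trains each
#' on the data, scores factual-outcome discrimination (AUC of the assigned
#' arm's head) on the internal validation split, and returns the best
#' configuration with the full trial log.
#'
#' @param space Named list of candidate value vectors; names must match
#'   [repflow_config()] arguments.
#' @param budget Number of trials (>= 1).
#' @param features,a,y Data.
#' @param seed Search seed.
#' @return List with `best_config`, `best_auc`, and `trials` (a tibble log,
#'   one row per trial).
#' @export
hyperparameter_search <- function(space, budget, features, a, y, seed = 1L) {
  if (budget < 1) stop("budget must be >= 1")
  set.seed(seed)
  draws <- lapply(seq_len(budget), function(i) {
    lapply(space, function(v) v[[sample.int(length(v), 1)]])
  })
  trials <- purrr::map_dfr(seq_len(budget), function(i) {
    cfg <- do.call(repflow_config, draws[[i]])
    auc <- tryCatch({
      set.seed(seed + i)
      val_idx <- stratified_val_split(a, y, cfg$val_frac)
      s0 <- train_stage0(features, a, y, cfg, val_idx)
      fw <- stage0_forward(s0$params, features_subset(features, val_idx))
      p <- ifelse(a[val_idx] == 1L, fw$p1, fw$p0)
      discrimination_metrics(y[val_idx], p)["auc"]
    }, error = function(e) NA_real_)
    tibble::tibble(trial = i, auc = unname(auc),
                   config = list(draws[[i]]))
  })
  ok <- which(!is.na(trials$auc))
  if (length(ok) == 0) stop("all hyperparameter trials failed")
  best <- ok[which.max(trials$auc[ok])]
  list(best_config = do.call(repflow_config, draws[[best]]),
       best_auc = trials$auc[best], trials = trials)
}

#' @export
print.repflow_model <- function(x, ...) {
  cat("<repflow_model>\n")
  cat(sprintf("  representation dim %d, flow depth %d, lambda = %g\n",
              x$config$rep_dim, x$config$flow_depth, x$config$lambda))
  cat(sprintf("  trained on %d encounters (seed %d)\n", x$n_train, x$seed))
  cat(sprintf("  validation epochs: stage0 %d, stage1 %d, stage2 %d\n",
              length(x$history$stage0), length(x$history$stage1),
              length(x$history$stage2)))
  invisible(x)
}
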
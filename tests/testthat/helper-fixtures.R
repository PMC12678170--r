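# Shared fixtures, generated in code.

# A small confounded cohort + features, fixed seed.
small_cohort <- function(n = 300, gamma = 1, tau_fn = "constant", seed = 42,
                         ...) {
  cfg <- sim_config(n_encounters = n, gamma_hidden = gamma,
                    tau_fn_id = tau_fn, seed = seed, ...)
  list(cfg = cfg, cohort = simulate_cohort(cfg))
}

# Randomly parameterised flow (departing from the identity) for invertibility
# properties.
random_flow <- function(n_layers = 3, cond_dim = 4, hidden = 16, sd = 0.3,
                        seed = 1) {
  set.seed(seed)
  fl <- flowcfr:::flow_new(n_layers, cond_dim, hidden)
  for (k in seq_len(n_layers)) {
    fl$layers[[k]]$W2 <- matrix(rnorm(2 * hidden, sd = sd), hidden, 2)
    fl$layers[[k]]$b2 <- rnorm(2, sd = sd)
    fl$layers[[k]]$lgamma <- rnorm(1, sd = sd)
  }
  fl
}

# An untrained model skeleton (identity flows, random stage 0) around a
# feature object; enough structure for inference-mechanics tests.
skeleton_model <- function(features, rep_dim = 4, flow_depth = 2, seed = 7) {
  set.seed(seed)
  s0 <- flowcfr:::stage0_new(ncol(features$x), length(features$channels),
                             hidden = 8L, rep_dim = rep_dim)
  structure(
    list(stage0 = s0,
         flow1 = flowcfr:::flow_new(flow_depth, rep_dim + 1L, 8L),
         flow2 = flowcfr:::flow_new(flow_depth, rep_dim, 8L),
         config = repflow_config(rep_dim = rep_dim, flow_depth = flow_depth,
                                 n_mc = 64L),
         seed = seed, n_train = nrow(features$x),
         history = list(stage0 = 0, stage1 = 0, stage2 = 0)),
    class = "repflow_model")
}

# One small trained model shared by several test files (built lazily once).
trained_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- small_cohort(n = 500, gamma = 0.5, seed = 11)
      feats <- features_from_cohort(sc$cohort)
      cfg <- repflow_config(epochs = 15L, patience = 5L, batch_size = 64L,
                            hidden = 16L, rep_dim = 4L)
      m <- repflow_train(feats, sc$cohort$a, sc$cohort$y, cfg, seed = 3)
      cache <<- list(cohort = sc$cohort, features = feats, model = m)
    }
    cache
  }
})
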
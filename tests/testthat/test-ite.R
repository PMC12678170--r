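# ITE engines: banding, common random numbers, Monte-Carlo behaviour,
# baselines.

test_that("band classification follows the three-way rule with inclusive boundaries", {
  vals <- c(-0.01, -0.0011, -0.001, 0, 0.001, 0.0011, 0.01)
  expect_equal(
    as.character(classify_band(vals)),
    c("NIV_preferred", "NIV_preferred", "Indifferent", "Indifferent",
      "Indifferent", "HFNC_preferred", "HFNC_preferred"))
  expect_error(classify_band(NaN), "non-finite")
  expect_error(classify_band(0.1, band = -1), "band")
})

test_that("an arm-symmetric model yields an exactly zero effect", {
  sc <- small_cohort(n = 80, seed = 81)
  feats <- features_from_cohort(sc$cohort)
  m <- skeleton_model(feats)
  # flow1 ignores its arm input entirely: zero out the arm column weights
  m$flow1 <- random_flow(2, m$config$rep_dim + 1L, hidden = 8, seed = 31)
  for (k in seq_along(m$flow1$layers)) {
    m$flow1$layers[[k]]$W1[m$config$rep_dim + 1L, ] <- 0
  }
  ite <- estimate_ite(m, feats, n_mc = 32, seed = 2)
  expect_true(all(ite$ite == 0))
  expect_true(all(ite$band_label == "Indifferent"))
})

test_that("a degenerate flow mapping all latents to the event region returns 1", {
  sc <- small_cohort(n = 40, seed = 83)
  feats <- features_from_cohort(sc$cohort)
  m <- skeleton_model(feats)
  m$flow1$layers[[1]]$b2 <- c(50, 0)     # shift every sample far above 0
  p <- predict_counterfactual(m, feats, arm = 1, n_mc = 16, seed = 3)
  expect_true(all(p == 1))
  expect_error(predict_counterfactual(m, feats, arm = 1, n_mc = 0), "n_mc")
})

test_that("Monte-Carlo error shrinks at the root-n rate", {
  sc <- small_cohort(n = 12, seed = 85)
  feats <- features_from_cohort(sc$cohort)
  m <- skeleton_model(feats)
  m$flow1 <- random_flow(2, m$config$rep_dim + 1L, hidden = 8, seed = 33)
  se_at <- function(n_mc) {
    reps <- vapply(1:30, function(s) {
      mean(predict_counterfactual(m, feats, arm = 1, n_mc = n_mc, seed = s))
    }, numeric(1))
    sd(reps)
  }
  se <- vapply(c(16, 256), se_at, numeric(1))
  ratio <- se[1] / se[2]
  expect_gt(ratio, 4 / 2.2)     # ideal sqrt(256/16) = 4, generous factor
  expect_lt(ratio, 4 * 2.2)
})

test_that("the CFR baseline reads the heads directly and matches closed form", {
  sc <- small_cohort(n = 60, seed = 87)
  feats <- features_from_cohort(sc$cohort)
  m <- skeleton_model(feats, rep_dim = 2)
  # identical heads: exactly zero effect
  m$stage0$head_niv <- list(w = c(0.3, -0.2), b = 0.1)
  m$stage0$head_hfnc <- list(w = c(0.3, -0.2), b = 0.1)
  ite0 <- cfr_baseline_ite(m$stage0, feats)
  expect_true(all(ite0$ite == 0))

  # hand-set heads: logistic difference
  m$stage0$head_hfnc <- list(w = c(-0.1, 0.5), b = -0.3)
  ite1 <- cfr_baseline_ite(m$stage0, feats)
  phi <- encode(m$stage0, feats)
  p0 <- plogis(phi %*% c(0.3, -0.2) + 0.1)
  p1 <- plogis(phi %*% c(-0.1, 0.5) - 0.3)
  expect_equal(ite1$ite, drop(p0 - p1), tolerance = 1e-12)
  expect_equal(ite1$band_label, classify_band(ite1$ite))
  expect_error(cfr_baseline_ite(list(), feats), "untrained")
})

test_that("X-Learner recovers null and constant effects on simulations", {
  # null effect
  sc0 <- small_cohort(n = 2000, gamma = 0, tau_fn = "constant", seed = 91,
                      tau_value = 0)
  f0 <- features_from_cohort(sc0$cohort)
  x0 <- x_learner_ite(f0, sc0$cohort$a, sc0$cohort$y)
  expect_lte(mean(abs(x0$ite)), 0.03)

  # constant effect 0.10 (HFNC raises risk; ite = NIV - HFNC is negative)
  sc1 <- small_cohort(n = 2000, gamma = 0, tau_fn = "constant", seed = 93,
                      tau_value = 0.10)
  f1 <- features_from_cohort(sc1$cohort)
  x1 <- x_learner_ite(f1, sc1$cohort$a, sc1$cohort$y)
  expect_lte(abs(mean(-x1$ite) - 0.10), 0.04)

  # deterministic given seed and data
  expect_identical(x1, x_learner_ite(f1, sc1$cohort$a, sc1$cohort$y))
  expect_error(x_learner_ite(f1, rep(0L, 2000), sc1$cohort$y), "both arms")
})

test_that("engines emit schema-identical tables; missing forest backend skips", {
  sc <- small_cohort(n = 150, seed = 95)
  feats <- features_from_cohort(sc$cohort)
  m <- trained_fixture()$model
  # the fixture model was trained on different features; rebuild quickly
  fx <- trained_fixture()
  tbls <- list(
    estimate_ite(fx$model, fx$features, n_mc = 16, seed = 1),
    cfr_baseline_ite(fx$model$stage0, fx$features),
    x_learner_ite(fx$features, fx$cohort$a, fx$cohort$y)
  )
  for (tb in tbls) {
    expect_s3_class(tb, "flowcfr_ite")
    expect_named(tb, c("encounter_id", "engine_id", "p_imv_niv", "p_imv_hfnc",
                       "ite", "band_label", "n_mc"))
    expect_true(all(tb$p_imv_niv >= 0 & tb$p_imv_niv <= 1))
  }
  cf <- causal_forest_ite(feats, sc$cohort$a, sc$cohort$y)
  if (!requireNamespace("grf", quietly = TRUE)) {
    expect_s3_class(cf, "flowcfr_skipped")
    expect_match(cf$reason, "grf")
  } else {
    expect_s3_class(cf, "flowcfr_ite")
  }
})

test_that("estimated effect signs track the truth under sign-flipping heterogeneity", {
  sc <- small_cohort(n = 5000, gamma = 0, tau_fn = "sign_flip", seed = 97,
                     tau_value = 0.15)
  feats <- features_from_cohort(sc$cohort)
  coh <- sc$cohort
  xl <- x_learner_ite(feats, coh$a, coh$y)
  cm_x <- causal_metrics(xl, coh)
  expect_gte(cm_x["sign_accuracy"], 0.80)

  cfg <- repflow_config(epochs = 80L, patience = 15L, batch_size = 64L)
  m <- repflow_train(feats, coh$a, coh$y, cfg, seed = 7)
  rf <- estimate_ite(m, feats, n_mc = 256, seed = 7)
  cm_r <- causal_metrics(rf, coh)
  expect_gte(cm_r["sign_accuracy"], 0.80)
})
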
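# Concordance labelling, stratified rates, adjusted regression, metrics.

oracle_ite_tbl <- function(cohort, band = 0.001) {
  flowcfr:::new_ite_tbl(cohort$encounter_id, "oracle",
                        cohort$p0, cohort$p1, band, 0L)
}

test_that("the 3x2 recommendation-by-actual grid yields the documented indicators", {
  coh <- tibble::tibble(
    encounter_id = 1:6,
    a = rep(c(0L, 1L), 3),
    y = 0L, y_mort_hospice = 0L,
    age = 60, sex = 0L, sofa_t0 = 1L, cci = 2, risk_t0 = 0.5
  )
  est <- flowcfr:::new_ite_tbl(1:6, "test",
                               p_niv = c(0.2, 0.2, 0.4, 0.4, 0.3, 0.3),
                               p_hfnc = c(0.4, 0.4, 0.2, 0.2, 0.3, 0.3),
                               band = 0.001, n_mc = 0L)
  rec <- label_concordance(est, coh)
  # rows 1-2 NIV_preferred, 3-4 HFNC_preferred, 5-6 Indifferent
  expect_equal(rec$niv_concordant, c(1L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(rec$hfnc_concordant, c(0L, 0L, 0L, 1L, 0L, 0L))
  expect_true(all(rec$niv_concordant + rec$hfnc_concordant <= 1))
  expect_error(label_concordance(est[c(1, 1, 2), ], coh), "duplicate")
})

test_that("group rates match manual counts and leave empty cells undefined", {
  coh <- tibble::tibble(
    encounter_id = 1:8,
    a = c(0L, 0L, 0L, 1L, 1L, 1L, 0L, 1L),
    y = c(1L, 0L, 0L, 1L, 1L, 0L, 1L, 0L),
    y_mort_hospice = 0L, age = 60, sex = 0L, sofa_t0 = 1L, cci = 2,
    risk_t0 = 0.5)
  ite <- c(-0.1, -0.1, 0.1, 0.1, 0.1, -0.1, -0.1, 0.1)
  est <- flowcfr:::new_ite_tbl(1:8, "test", p_niv = 0.3 + ite,
                               p_hfnc = 0.3, band = 0.001, n_mc = 0L)
  rec <- label_concordance(est, coh)
  rt <- outcome_rates_by_group(rec)
  # NIV-concordant: encounters 1,2,7 (a=0, NIV pref) -> events 1,0,1
  expect_equal(rt$rate[rt$actual == "NIV" & rt$concordant], 2 / 3)
  # HFNC-concordant: encounters 4,5,8 -> events 1,1,0
  expect_equal(rt$rate[rt$actual == "HFNC" & rt$concordant], 2 / 3)
  # NIV-discordant: encounter 3 only (HFNC-preferred, received NIV), y = 0
  expect_equal(rt$rate[rt$actual == "NIV" & !rt$concordant], 0 / 1)
  expect_true(all(rt$rate >= 0 & rt$rate <= 1, na.rm = TRUE))

  # all-concordant toy set: discordant cells undefined, not zero
  rec_c <- rec[rec$niv_concordant + rec$hfnc_concordant == 1, ]
  rt_c <- outcome_rates_by_group(rec_c)
  expect_true(all(is.na(rt_c$rate[!rt_c$concordant])))
})

test_that("single-binary-covariate logistic fit equals the contingency cross-ratio", {
  set.seed(11)
  for (r in 1:20) {
    repeat {
      x <- rbinom(200, 1, 0.4)
      p <- plogis(-0.5 + runif(1, -1.5, 1.5) * x)
      y <- rbinom(200, 1, p)
      tab <- table(factor(x, 0:1), factor(y, 0:1))
      if (all(tab > 0)) break
    }
    fit <- glm(y ~ x, family = binomial())
    or_fit <- exp(coef(fit)["x"])
    or_tab <- (tab["1", "1"] * tab["0", "0"]) / (tab["1", "0"] * tab["0", "1"])
    expect_equal(unname(or_fit), unname(or_tab), tolerance = 1e-6)

    # and through the package surface with constant adjusters dropped
    df <- tibble::tibble(outcome_imv = y, niv_concordant = x)
    res <- fit_concordance_logistic(df, covariates = character(0),
                                    indicators = "niv_concordant")
    or_pkg <- res$table$odds_ratio[res$table$term == "niv_concordant"]
    expect_equal(or_pkg, unname(or_tab), tolerance = 1e-6)
  }
})

test_that("null concordance covers OR = 1 in at least 90% of simulated fits", {
  set.seed(21)
  cover <- vapply(1:50, function(r) {
    n <- 400
    df <- tibble::tibble(
      outcome_imv = rbinom(n, 1, 0.3),
      niv_concordant = rbinom(n, 1, 0.4),
      age = rnorm(n, 60, 10), sex = rbinom(n, 1, 0.5),
      sofa_t0 = rpois(n, 2), cci = rpois(n, 2), risk_t0 = runif(n))
    tb <- tidy(fit_concordance_logistic(df, indicators = "niv_concordant"))
    row <- tb[tb$term == "niv_concordant", ]
    row$conf_low <= 1 && 1 <= row$conf_high
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("rank-deficiency and separation produce explicit diagnostics", {
  n <- 100
  df <- tibble::tibble(
    outcome_imv = rbinom(n, 1, 0.5),
    niv_concordant = rbinom(n, 1, 0.5),
    age = rnorm(n), sex = rbinom(n, 1, 0.5), sofa_t0 = rpois(n, 2),
    cci = rpois(n, 2), risk_t0 = runif(n))
  df$dup <- df$age
  expect_error(fit_concordance_logistic(df, covariates = c("age", "dup"),
                                        indicators = "niv_concordant"),
               "collinear")
  sep <- df
  sep$outcome_imv <- as.integer(sep$age > 0)
  expect_error(fit_concordance_logistic(sep, covariates = "age",
                                        indicators = "niv_concordant"),
               "separation")
})

test_that("discrimination metrics agree with all-pairs counting", {
  expect_equal(unname(discrimination_metrics(c(0, 0, 1, 1),
                                             c(0.1, 0.2, 0.8, 0.9))["auc"]), 1)
  expect_equal(unname(discrimination_metrics(c(1, 1, 0, 0),
                                             c(0.1, 0.2, 0.8, 0.9))["auc"]), 0)
  set.seed(31)
  for (r in 1:10) {
    y <- rbinom(10, 1, 0.5)
    if (length(unique(y)) < 2) y <- c(0, 1, y[-(1:2)])
    s <- sample(seq(0.1, 1, by = 0.1), 10, replace = TRUE)  # forces ties
    pos <- s[y == 1]; neg <- s[y == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(unname(discrimination_metrics(y, s)["auc"]), mean(pairs),
                 tolerance = 1e-12)
  }
  expect_error(discrimination_metrics(rep(1, 5), rnorm(5)), "both classes")
})

test_that("pr-auc matches a hand-stepped average precision on a toy case", {
  y <- c(1, 0, 1, 1, 0, 0)
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  # descending scores: precision at each positive = 1/1, 2/3, 3/4
  expect_equal(unname(discrimination_metrics(y, s)["pr_auc"]),
               (1 / 3) * (1 + 2 / 3 + 3 / 4), tolerance = 1e-12)
})

test_that("causal metrics recover shifts and vanish at the truth", {
  coh <- small_cohort(n = 200, seed = 41)$cohort
  est <- oracle_ite_tbl(coh)
  cm <- causal_metrics(est, coh)
  expect_equal(unname(cm["pehe"]), 0, tolerance = 1e-12)
  expect_equal(unname(cm["ate_bias"]), 0, tolerance = 1e-12)
  expect_equal(unname(cm["sign_accuracy"]), 1)

  shifted <- est
  shifted$p_imv_hfnc <- pmin(shifted$p_imv_hfnc + 0.1, 1)
  keep <- shifted$p_imv_hfnc == est$p_imv_hfnc + 0.1   # unclamped rows
  cm2 <- causal_metrics(shifted[keep, ], coh[keep, ])
  expect_equal(unname(cm2["ate_bias"]), 0.1, tolerance = 1e-12)

  set.seed(5)
  small <- est[1:20, ]
  small$p_imv_hfnc <- pmin(pmax(small$p_imv_hfnc + rnorm(20, 0, 0.05), 0), 1)
  cm3 <- causal_metrics(small, coh[1:20, ])
  tau_hat <- small$p_imv_hfnc - small$p_imv_niv
  expect_equal(unname(cm3["pehe"]),
               sqrt(mean((tau_hat - coh$tau_true[1:20])^2)), tolerance = 1e-12)
  expect_error(causal_metrics(est[1:10, ], coh), "length")
})

test_that("planted benefit shows up as lower concordant rates and protective ORs", {
  cfg <- sim_config(n_encounters = 4000, gamma_hidden = 0.5,
                    tau_fn_id = "sign_flip", tau_value = 0.15, seed = 57)
  coh <- simulate_cohort(cfg)
  set.seed(58)
  follow <- rbinom(nrow(coh), 1, 0.5) == 1          # half get the better arm
  better <- ifelse(coh$tau_true > 0, 0L, 1L)        # arm with lower risk
  coh$a <- ifelse(follow, better, 1L - better)
  coh$y <- ifelse(coh$a == 1L, coh$y1, coh$y0)
  est <- oracle_ite_tbl(coh)
  rec <- label_concordance(est, coh)
  rt <- outcome_rates_by_group(rec)
  for (arm in c("NIV", "HFNC")) {
    expect_lt(rt$rate[rt$actual == arm & rt$concordant],
              rt$rate[rt$actual == arm & !rt$concordant])
  }
  tb <- tidy(fit_concordance_logistic(rec))
  for (trm in c("niv_concordant", "hfnc_concordant")) {
    expect_lt(tb$odds_ratio[tb$term == trm], 1)
    expect_lt(tb$p_value[tb$term == trm], 0.05)
  }
})
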
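# Treatment-concordance outcome analysis.
#
# Concordance compares the arm recommended by an ITE engine at the decision
# time with the arm actually administered first; later switches do not change
# the encounter-level label.  Outcome rates are stratified over the four
# (actual arm) x (concordant / discordant) cells, and adjusted associations
# come from multivariable logistic regressions with Wald inference.
# Encounters with an Indifferent recommendation contribute 0 to both
# concordance indicators and thus sit in the regression reference group.

#' Label treatment concordance for a cohort
#'
#' @param estimates A `flowcfr_ite` tibble (one row per encounter).
#' @param cohort Cohort tibble with `encounter_id`, actual treatment `a`
#'   (0 = NIV, 1 = HFNC), outcome `y`, optionally `y_mort_hospice`, and the
#'   adjuster columns `age`, `sex`, `sofa_t0`, `cci`, `risk_t0`.
#' @return A `flowcfr_concordance` tibble: recommendation, actual arm, the
#'   two concordance indicators, outcomes and adjusters.
#' @export
label_concordance <- function(estimates, cohort) {
  if (anyDuplicated(estimates$encounter_id) > 0) {
    stop("duplicate encounter_id in estimates")
  }
  df <- dplyr::inner_join(
    estimates[, c("encounter_id", "engine_id", "ite", "band_label")],
    cohort, by = "encounter_id")
  if (nrow(df) != nrow(estimates)) {
    stop("estimates and cohort do not cover the same encounters")
  }
  out <- df |>
    dplyr::transmute(
      encounter_id = .data$encounter_id,
      engine_id = .data$engine_id,
      recommended = .data$band_label,
      actual = factor(ifelse(.data$a == 1L, "HFNC", "NIV"),
                      levels = c("NIV", "HFNC")),
      niv_concordant = as.integer(.data$band_label == "NIV_preferred" &
                                    .data$a == 0L),
      hfnc_concordant = as.integer(.data$band_label == "HFNC_preferred" &
                                     .data$a == 1L),
      outcome_imv = .data$y,
      outcome_mort_hospice = if ("y_mort_hospice" %in% names(df)) {
        .data$y_mort_hospice
      } else {
        NA_integer_
      },
      age = .data$age, sex = .data$sex, sofa_t0 = .data$sofa_t0,
      cci = .data$cci, risk_t0 = .data$risk_t0
    )
  class(out) <- c("flowcfr_concordance", class(out))
  out
}

#' Outcome rates by actual arm and concordance
#'
#' @param records A `flowcfr_concordance` tibble.
#' @param outcome Column to summarise (`"outcome_imv"` or
#'   `"outcome_mort_hospice"`).
#' @return Tibble with one row per (actual arm) x (concordant / discordant)
#'   cell: `n`, `events`, `rate` (`NA`, not 0, for empty cells).
#' @export
outcome_rates_by_group <- function(records, outcome = "outcome_imv") {
  if (nrow(records) == 0) stop("no records")
  grid <- tidyr::expand_grid(actual = factor(c("NIV", "HFNC"),
                                             levels = c("NIV", "HFNC")),
                             concordant = c(TRUE, FALSE))
  obs <- records |>
    dplyr::mutate(concordant = (.data$niv_concordant +
                                  .data$hfnc_concordant) == 1L) |>
    dplyr::group_by(.data$actual, .data$concordant) |>
    dplyr::summarise(n = dplyr::n(),
                     events = sum(.data[[outcome]]), .groups = "drop")
  out <- grid |>
    dplyr::left_join(obs, by = c("actual", "concordant")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  events = dplyr::coalesce(.data$events, 0L),
                  rate = dplyr::if_else(.data$n > 0, .data$events / .data$n,
                                        NA_real_),
                  outcome = outcome)
  class(out) <- c("flowcfr_rates", class(out))
  out
}

#' Adjusted logistic regression of an outcome on concordance
#'
#' Maximum-likelihood logistic regression of the outcome on the two
#' concordance indicators, adjusting for age, sex (female = 1), SOFA at the
#' decision hour, comorbidity index and risk score.  Reports Wald odds
#' ratios, 95% confidence intervals and p-values, plus in-sample AUC.
#'
#' @param records A `flowcfr_concordance` tibble.
#' @param outcome Outcome column name.
#' @param covariates Adjuster columns (besides the concordance indicators).
#' @param indicators Concordance indicator columns to include (both by
#'   default; a single indicator supports reduced designs).
#' @return A `flowcfr_logistic` object; use [tidy()] for the OR table and
#'   [glance()] for model-level summaries.
#' @export
fit_concordance_logistic <- function(records, outcome = "outcome_imv",
                                     covariates = c("age", "sex", "sofa_t0",
                                                    "cci", "risk_t0"),
                                     indicators = c("niv_concordant",
                                                    "hfnc_concordant")) {
  terms <- c(indicators, covariates)
  df <- records[, c(outcome, terms)]
  names(df)[1] <- ".y"
  if (length(unique(df$.y)) < 2L) stop("outcome has a single class")

  Xd <- cbind("(Intercept)" = 1, as.matrix(df[, terms]))
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrX$pivot[(qrX$rank + 1L):ncol(Xd)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }

  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop("perfect separation detected in the logistic fit", call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    odds_ratio = exp(unname(est)),
    conf_low = exp(unname(est - 1.96 * se)),
    conf_high = exp(unname(est + 1.96 * se)),
    p_value = unname(p)
  )
  auc <- unname(discrimination_metrics(df$.y, fitted(fit))["auc"])
  structure(list(fit = fit, table = tab, auc = auc, n = nrow(df),
                 outcome = outcome),
            class = "flowcfr_logistic")
}

#' @export
print.flowcfr_logistic <- function(x, ...) {
  cat(sprintf("<flowcfr_logistic> outcome %s, n = %d, AUC = %.3f\n",
              x$outcome, x$n, x$auc))
  print(x$table[-1, c("term", "odds_ratio", "conf_low", "conf_high",
                      "p_value")], digits = 3)
  invisible(x)
}

#' @rdname fit_concordance_logistic
#' @param x A `flowcfr_logistic` object.
#' @param ... Unused.
#' @method tidy flowcfr_logistic
#' @export
tidy.flowcfr_logistic <- function(x, ...) x$table

#' @rdname fit_concordance_logistic
#' @method glance flowcfr_logistic
#' @export
glance.flowcfr_logistic <- function(x, ...) {
  tibble::tibble(n = x$n, auc = x$auc,
                 deviance = x$fit$deviance,
                 null_deviance = x$fit$null.deviance,
                 aic = x$fit$aic)
}

#' Discrimination metrics: ROC AUC and precision-recall AUC
#'
#' Rank-based AUC (ties averaged; equals the Mann-Whitney statistic) and the
#' interpolation-free precision-recall AUC (average precision over distinct
#' score thresholds).
#'
#' @param y_true Binary labels (both classes required).
#' @param y_score Numeric scores, higher = more likely positive.
#' @return Named vector `c(auc = , pr_auc = )`.
#' @export
discrimination_metrics <- function(y_true, y_score) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1L); n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required")
  r <- rank(y_score)
  auc <- (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ## average precision over distinct thresholds, ties grouped
  ord <- order(y_score, decreasing = TRUE)
  ys <- y_true[ord]; ss <- y_score[ord]
  grp <- cumsum(!duplicated(ss))
  tp_g <- tapply(ys, grp, sum)
  n_g <- tapply(rep(1L, length(ys)), grp, sum)
  tp <- cumsum(tp_g); np <- cumsum(n_g)
  prec <- tp / np
  rec <- tp / n1
  pr_auc <- sum(diff(c(0, rec)) * prec)
  c(auc = auc, pr_auc = pr_auc)
}

#' Ground-truth causal error metrics on synthetic data
#'
#' Converts the estimates to the treated-minus-control (HFNC minus NIV) risk
#' difference `tau_hat = p_imv_hfnc - p_imv_niv` and compares with the stored
#' `tau_true`:
#' PEHE (root-mean-square individual error), ATE bias (mean difference) and
#' the sign accuracy over encounters with `|tau_true| > band`.
#'
#' @param estimates A `flowcfr_ite` tibble.
#' @param truth Cohort tibble carrying `encounter_id` and `tau_true`.
#' @param band Indifference half-width excluded from sign accuracy.
#' @return Named vector `c(pehe = , ate_bias = , sign_accuracy = )`.
#' @export
causal_metrics <- function(estimates, truth, band = BAND_DEFAULT) {
  if (nrow(estimates) != nrow(truth)) stop("length mismatch")
  df <- dplyr::inner_join(
    estimates[, c("encounter_id", "p_imv_niv", "p_imv_hfnc")],
    truth[, c("encounter_id", "tau_true")], by = "encounter_id")
  if (nrow(df) != nrow(estimates)) stop("encounter ids do not match")
  tau_hat <- df$p_imv_hfnc - df$p_imv_niv
  err <- tau_hat - df$tau_true
  het <- abs(df$tau_true) > band
  sign_acc <- if (any(het)) {
    mean(sign(tau_hat[het]) == sign(df$tau_true[het]))
  } else {
    NA_real_
  }
  c(pehe = sqrt(mean(err^2)),
    ate_bias = mean(tau_hat) - mean(df$tau_true),
    sign_accuracy = sign_acc)
}
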
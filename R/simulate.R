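# Synthetic ICU cohort generator.
#
# Emulates the observational setting the estimator is built for: two
# respiratory-support arms (NIV = 0, HFNC = 1) assigned with confounding by
# measured covariates and by a hidden severity latent, a binary outcome
# (invasive mechanical ventilation) with a configurable heterogeneous
# treatment effect on the risk-difference scale, encounter-level adjustment
# covariates (age, sex, SOFA, comorbidity index, risk score), and irregular
# hourly measurement streams feeding the preprocessing rules.  Ground-truth
# potential outcomes are stored so causal error metrics are computable.

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_cohort()].
#'
#' @param n_encounters Number of encounters (>= 2).
#' @param d_measured Dimension of the measured covariate vector `x`.
#' @param gamma_hidden Hidden-confounding strength (>= 0): the latent severity
#'   `u ~ N(0,1)` enters both the treatment-selection logit and the outcome
#'   logit with this coefficient.  0 switches hidden confounding off.
#' @param beta_select Treatment-selection coefficients on `x` (padded with
#'   zeros or truncated to `d_measured`); with the defaults, selection acts on
#'   x1..x3 only.
#' @param tau_fn_id True treatment-effect function on the risk-difference
#'   scale: `"constant"` (`tau_value` everywhere), `"linear"`
#'   (`tau_value + tau_slope * x1`, clamped to \[-0.5, 0.5\]) or
#'   `"sign_flip"` (`tau_value * sign(x4)`; the modifier is a covariate that
#'   does not enter the baseline-risk surface, so effect sign and baseline
#'   risk are independent).
#' @param tau_value Effect magnitude; the HFNC-minus-NIV risk difference.
#' @param tau_slope Slope for the linear effect function.
#' @param base_rate Target factual outcome prevalence in (0, 1); the outcome
#'   intercept is calibrated by bisection to reach it.
#' @param ts_hours Length of the longitudinal window in hours (>= 2).
#' @param missing_rate Per-channel, per-hour probability that no measurement
#'   is recorded, in [0, 1).
#' @param channels Character vector of measurement channel names.
#' @param seed Integer seed governing every random draw.
#' @return A validated list of class `flowcfr_sim_config`.
#' @export
sim_config <- function(n_encounters = 2000,
                       d_measured = 6,
                       gamma_hidden = 1,
                       beta_select = c(0.8, -0.5, 0.4),
                       tau_fn_id = c("constant", "linear", "sign_flip"),
                       tau_value = 0.10,
                       tau_slope = 0.08,
                       base_rate = 0.25,
                       ts_hours = 96,
                       missing_rate = 0.3,
                       channels = c("heart_rate", "resp_rate", "spo2",
                                    "sbp", "lactate", "creatinine"),
                       seed = 1L) {
  tau_fn_id <- match.arg(tau_fn_id)
  if (!is.numeric(n_encounters) || n_encounters < 2) {
    stop("n_encounters must be >= 2")
  }
  if (!is.numeric(gamma_hidden) || !is.finite(gamma_hidden) || gamma_hidden < 0) {
    stop("gamma_hidden must be a finite value >= 0")
  }
  if (!all(is.finite(beta_select))) stop("beta_select must be finite")
  if (!is.finite(tau_value) || !is.finite(tau_slope)) stop("tau parameters must be finite")
  if (base_rate <= 0 || base_rate >= 1) stop("base_rate must lie in (0, 1)")
  if (ts_hours < 2) stop("ts_hours must be >= 2")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  beta <- c(beta_select, numeric(d_measured))[seq_len(d_measured)]
  structure(
    list(n_encounters = as.integer(n_encounters), d_measured = as.integer(d_measured),
         gamma_hidden = gamma_hidden, beta_select = beta, tau_fn_id = tau_fn_id,
         tau_value = tau_value, tau_slope = tau_slope, base_rate = base_rate,
         ts_hours = as.integer(ts_hours), missing_rate = missing_rate,
         channels = channels, seed = as.integer(seed)),
    class = "flowcfr_sim_config"
  )
}

# The sign-flipping modifier is a covariate outside the baseline-risk surface
# (x4 when available): tying the effect sign to a baseline-risk covariate
# would make within-arm concordant/discordant groups differ in composition,
# so raw benefit comparisons would reflect case mix instead of the effect.
tau_fn <- function(cfg, X) {
  mod <- X[, min(4L, ncol(X))]
  switch(cfg$tau_fn_id,
    constant = rep(cfg$tau_value, nrow(X)),
    linear = pmin(pmax(cfg$tau_value + cfg$tau_slope * X[, 1], -0.5), 0.5),
    sign_flip = cfg$tau_value * sign(mod)
  )
}

#' Generate a confounded synthetic cohort with known ground truth
#'
#' Draws measured covariates `x ~ N(0, I)` and a hidden severity latent
#' `u ~ N(0, 1)`; assigns treatment with propensity
#' `plogis(x %*% beta_select + gamma_hidden * u)`; sets a base event
#' probability `plogis(b0 + f(x) + gamma_hidden * u)` with the intercept `b0`
#' calibrated by bisection so the factual outcome prevalence matches
#' `base_rate`, and splits the treatment effect symmetrically about it:
#' `p0 = base - tau(x)/2` under NIV and `p1 = base + tau(x)/2` under HFNC
#' (each clamped to \[0, 1\]).  Both potential outcomes are drawn with a single shared uniform
#' variate per encounter (monotone coupling), so the stored `tau_true = p1 -
#' p0` is exactly the individual risk difference.  Adjustment covariates
#' (age, sex, SOFA at the trigger hour, comorbidity index, risk score) are
#' noisy transforms of `(x, u)` so downstream adjusted regressions face
#' genuine confounding.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with one row per encounter: `encounter_id`, covariates
#'   `x1..xd`, `u_true`, treatment `a` (0 = NIV, 1 = HFNC), factual outcome
#'   `y` (IMV), potential outcomes `y0`, `y1`, probabilities `p0`, `p1`,
#'   `tau_true = p1 - p0`, secondary outcome `y_mort_hospice`, trigger hour
#'   `t0_hour`, and adjusters `age`, `sex`, `sofa_t0`, `cci`, `risk_t0`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_encounters = 200, seed = 7))
#' mean(cohort$y)
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "flowcfr_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_encounters
  d <- cfg$d_measured
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("x", seq_len(d))))
  u <- rnorm(n)

  prop <- plogis(drop(X %*% cfg$beta_select) + cfg$gamma_hidden * u)
  a <- rbinom(n, 1L, prop)

  # nonlinear measured risk surface (fixed shape; strength comparable to x)
  f_base <- 0.9 * X[, 1] + 0.6 * X[, 2] - 0.4 * X[, 3] + 0.3 * X[, 1] * X[, 2]
  eta <- f_base + cfg$gamma_hidden * u
  tau <- tau_fn(cfg, X)

  # The effect is split symmetrically about a shared base risk:
  # p_niv = base - tau/2, p_hfnc = base + tau/2.  Both arms then carry the
  # treatment effect, and tau_true = p1 - p0 stays exact away from clamping.
  # calibrate intercept so the factual event rate hits base_rate
  rate_at <- function(b0) {
    pb <- plogis(b0 + eta)
    p0 <- pmin(pmax(pb - tau / 2, 0), 1)
    p1 <- pmin(pmax(pb + tau / 2, 0), 1)
    mean(ifelse(a == 1L, p1, p0))
  }
  lo <- -20; hi <- 20
  if (rate_at(lo) > cfg$base_rate || rate_at(hi) < cfg$base_rate) {
    stop("base_rate unreachable by intercept calibration")
  }
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (rate_at(mid) < cfg$base_rate) lo <- mid else hi <- mid
  }
  b0 <- (lo + hi) / 2

  pb <- plogis(b0 + eta)
  p0 <- pmin(pmax(pb - tau / 2, 0), 1)
  p1 <- pmin(pmax(pb + tau / 2, 0), 1)
  v <- runif(n)                       # shared noise: monotone coupling
  y0 <- as.integer(v < p0)
  y1 <- as.integer(v < p1)
  y <- ifelse(a == 1L, y1, y0)

  # secondary outcome: mortality-or-hospice, correlated with severity and IMV
  p_mh <- plogis(-1.6 + 0.8 * cfg$gamma_hidden * u + 0.5 * X[, 1] + 1.0 * y)
  y_mh <- rbinom(n, 1L, p_mh)

  t0_hour <- pmin(cfg$ts_hours - 1L, 4L + rpois(n, 8))

  adj <- tibble::tibble(
    age = round(pmin(pmax(62 + 10 * X[, 1] + 4 * rnorm(n), 18), 100)),
    sex = rbinom(n, 1L, plogis(0.15 * X[, 2])),
    sofa_t0 = pmin(24L, pmax(0L, as.integer(round(2 + 1.4 * u + 0.8 * X[, 3] + rnorm(n))))),
    cci = rpois(n, pmax(0.2, 2 + 0.8 * X[, 4] + 0.5 * u)),
    risk_t0 = plogis(0.9 * u + 0.5 * X[, 1] + 0.4 * rnorm(n))
  )

  dplyr::bind_cols(
    tibble::tibble(encounter_id = seq_len(n)),
    tibble::as_tibble(X),
    tibble::tibble(u_true = u, propensity = prop, a = a,
                   y = y, y0 = y0, y1 = y1, p0 = p0, p1 = p1,
                   tau_true = p1 - p0, y_mort_hospice = y_mh,
                   t0_hour = t0_hour),
    adj
  )
}

#' Generate irregular hourly measurement streams for a cohort
#'
#' For every encounter and channel, draws measurements on an hourly lattice
#' with per-hour dropout at `missing_rate` and within-hour timestamp jitter
#' (occasionally two measurements fall in the same hour, exercising the median
#' binning rule).  Channel values follow a channel-specific baseline plus a
#' severity component proportional to the encounter's hidden latent that ramps
#' up towards the trigger hour, so preprocessing output carries causal signal.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @param cfg The same [sim_config()] used to generate it.
#' @return A long tibble: `encounter_id`, `channel`, `time_hours` (real),
#'   `value`, sorted by encounter, channel, time.
#' @export
simulate_longitudinal <- function(cohort, cfg) {
  stopifnot(inherits(cfg, "flowcfr_sim_config"))
  if (cfg$ts_hours < 2) stop("ts_hours must be >= 2")
  set.seed(cfg$seed + 1L)
  H <- cfg$ts_hours
  chans <- cfg$channels
  base_level <- stats::setNames(
    rep_len(c(85, 18, 97, 120, 1.5, 1.0), length(chans)), chans)
  sev_load <- stats::setNames(
    rep_len(c(10, 4, -3, -12, 1.2, 0.5), length(chans)), chans)

  out <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    u <- cohort$u_true[i]
    t0 <- cohort$t0_hour[i]
    ramp <- plogis((seq_len(H) - 1 - t0 + 4) / 3)   # severity rises into t0
    purrr::map_dfr(chans, function(ch) {
      keep <- runif(H) >= cfg$missing_rate
      hrs <- which(keep) - 1L
      if (length(hrs) == 0L) return(NULL)
      # occasional second measurement within the hour
      extra <- hrs[runif(length(hrs)) < 0.15]
      tt <- sort(c(hrs + runif(length(hrs)), extra + runif(length(extra))))
      vals <- base_level[ch] + sev_load[ch] * u * ramp[floor(tt) + 1L] +
        stats::rnorm(length(tt), sd = abs(base_level[ch]) * 0.02 + 0.1)
      tibble::tibble(encounter_id = cohort$encounter_id[i], channel = ch,
                     time_hours = tt, value = vals)
    })
  })
  dplyr::arrange(out, .data$encounter_id, .data$channel, .data$time_hours)
}

#' Stand-in risk trigger: first hour a fixed logistic score crosses a threshold
#'
#' A simple fixed-weight logistic score over the current (hourly-binned,
#' carried-forward) channel values, evaluated from hour 4 onwards; returns the
#' first hour at which the score meets or exceeds `threshold`, or `NA` if it
#' never does.  This is a structural stand-in for an upstream deterioration
#' model that defines the decision time T0; it makes no claim to clinical
#' validity.
#'
#' @param record Long tibble for a single encounter (columns `channel`,
#'   `time_hours`, `value`).
#' @param threshold Score threshold in [0, 1].
#' @param weights Named numeric vector of per-channel weights applied to
#'   z-scored channel values (defaults to 1 for every observed channel).
#' @param intercept Score intercept on the logit scale.
#' @return Integer hour of first crossing (>= 4), or `NA_integer_`.
#' @export
risk_trigger_t0 <- function(record, threshold = 0.8, weights = NULL,
                            intercept = 0) {
  max_t <- if (nrow(record) == 0) 0 else max(record$time_hours)
  if (max_t < 4) {
    warning("record shorter than 4 hours; no trigger possible")
    return(NA_integer_)
  }
  hours <- seq(4L, floor(max_t))
  grid <- bin_hourly(record, n_hours = floor(max_t) + 1L)
  filled <- carry_forward(grid)
  chans <- unique(filled$channel)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(chans)), chans)
  wide <- tidyr::pivot_wider(filled, id_cols = "hour",
                             names_from = "channel", values_from = "value")
  for (h in hours) {
    row <- wide[wide$hour == h, , drop = FALSE]
    vals <- vapply(names(weights), function(ch) {
      v <- if (ch %in% names(row)) row[[ch]] else NA_real_
      if (length(v) == 0 || is.na(v)) 0 else v
    }, numeric(1))
    score <- plogis(intercept + sum(weights * vals))
    if (score >= threshold) return(as.integer(h))
  }
  NA_integer_
}

#' Write a cohort and its longitudinal records as delimited text
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param longitudinal Optional tibble from [simulate_longitudinal()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, longitudinal = NULL, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, "cohort.csv")
  readr::write_csv(cohort, paths)
  if (!is.null(longitudinal)) {
    lp <- file.path(dir, "longitudinal.csv")
    readr::write_csv(longitudinal, lp)
    paths <- c(paths, lp)
  }
  invisible(paths)
}
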
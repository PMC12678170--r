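# Counterfactual inference and ITE estimation.
#
# Sign convention (pinned to the grouping rule of the concordance analysis):
# ite = P(IMV | NIV) - P(IMV | HFNC).  A negative value means lower intubation
# risk under NIV, so ite < -band labels the encounter NIV-preferred and
# ite > band HFNC-preferred; |ite| <= band (default 0.001, boundary inclusive)
# is Indifferent.

BAND_DEFAULT <- 0.001

#' Predicted counterfactual event probability under one arm
#'
#' Draws `n_mc` standard-normal latents, pushes them through the adjustment
#' flow (conditioned on the representation) and the outcome flow (conditioned
#' on representation and the requested arm), and returns the fraction of
#' samples falling in the event region of the dequantized outcome space.
#'
#' @param model A fitted `repflow_model`.
#' @param features `flowcfr_features` for the encounters to score.
#' @param arm 0 (NIV) or 1 (HFNC): the arm to condition on.
#' @param n_mc Number of Monte-Carlo latent draws (>= 1).
#' @param seed Seed for the latent draws.
#' @param stage `"stage2"` (default: adjustment flow then outcome flow) or
#'   `"stage1"` (outcome flow only, no hidden-confounder adjustment).
#' @return Numeric vector of event probabilities, one per encounter.
#' @export
predict_counterfactual <- function(model, features, arm, n_mc = model$config$n_mc,
                                   seed = 1L, stage = c("stage2", "stage1")) {
  stage <- match.arg(stage)
  if (n_mc < 1) stop("n_mc must be >= 1")
  phi <- stage0_forward(model$stage0, features)$phi
  n <- nrow(phi)
  set.seed(seed)
  Z <- matrix(rnorm(n * n_mc), n, n_mc)
  mc_probability(model, phi, arm, Z, stage)
}

mc_probability <- function(model, phi, arm, Z, stage) {
  n <- nrow(phi)
  cond1 <- cbind(phi, arm = rep(as.integer(arm), n))
  hits <- numeric(n)
  for (k in seq_len(ncol(Z))) {
    z <- Z[, k]
    if (stage == "stage2") z <- flow_forward(model$flow2, z, phi)$value
    yq <- flow_forward(model$flow1, z, cond1)$value
    hits <- hits + (yq > 0)        # logit((y+e)/2) > 0  <=>  y = 1
  }
  hits / ncol(Z)
}

#' Estimate individual treatment effects with the counterfactual model
#'
#' Computes both counterfactual probabilities with the same latent draws
#' (common random numbers, so a symmetric model yields an exactly zero
#' effect), takes `ite = p_imv_niv - p_imv_hfnc`, and assigns the three-way
#' band label.
#'
#' @inheritParams predict_counterfactual
#' @param band Indifference half-width on the risk-difference scale.
#' @return A tibble of class `flowcfr_ite`: `encounter_id`, `engine_id`,
#'   `p_imv_niv`, `p_imv_hfnc`, `ite`, `band_label`, `n_mc`.
#' @export
estimate_ite <- function(model, features, n_mc = model$config$n_mc, seed = 1L,
                         band = BAND_DEFAULT, stage = c("stage2", "stage1")) {
  stage <- match.arg(stage)
  if (n_mc < 1) stop("n_mc must be >= 1")
  phi <- stage0_forward(model$stage0, features)$phi
  n <- nrow(phi)
  set.seed(seed)
  Z <- matrix(rnorm(n * n_mc), n, n_mc)
  p_niv <- mc_probability(model, phi, 0L, Z, stage)
  p_hfnc <- mc_probability(model, phi, 1L, Z, stage)
  new_ite_tbl(features$encounter_id,
              engine_id = if (stage == "stage2") "repflow_cfr" else "repflow_stage1",
              p_niv, p_hfnc, band, n_mc)
}

new_ite_tbl <- function(encounter_id, engine_id, p_niv, p_hfnc, band, n_mc) {
  stopifnot(all(p_niv >= 0 & p_niv <= 1), all(p_hfnc >= 0 & p_hfnc <= 1))
  ite <- p_niv - p_hfnc
  out <- tibble::tibble(
    encounter_id = encounter_id,
    engine_id = engine_id,
    p_imv_niv = p_niv,
    p_imv_hfnc = p_hfnc,
    ite = ite,
    band_label = classify_band(ite, band),
    n_mc = as.integer(n_mc)
  )
  class(out) <- c("flowcfr_ite", class(out))
  out
}

#' Three-way treatment-preference label from an ITE value
#'
#' `ite < -band` maps to `NIV_preferred`, `ite > band` to `HFNC_preferred`,
#' and `|ite| <= band` (boundary inclusive) to `Indifferent`.
#'
#' @param ite Numeric vector of risk differences (NIV minus HFNC).
#' @param band Indifference half-width (default 0.001).
#' @return Factor with levels `NIV_preferred`, `HFNC_preferred`,
#'   `Indifferent`.
#' @export
classify_band <- function(ite, band = BAND_DEFAULT) {
  if (!all(is.finite(ite))) stop("classify_band: non-finite ite")
  if (band < 0) stop("band must be >= 0")
  lab <- ifelse(ite < -band, "NIV_preferred",
                ifelse(ite > band, "HFNC_preferred", "Indifferent"))
  factor(lab, levels = c("NIV_preferred", "HFNC_preferred", "Indifferent"))
}

#' CFR-baseline ITE from the Stage 0 heads
#'
#' Effect estimates read directly off the two factual heads (no flows).
#'
#' @param stage0 Stage 0 parameter list (field `stage0` of a fitted model).
#' @param features `flowcfr_features`.
#' @param band Indifference half-width.
#' @return A `flowcfr_ite` tibble with `engine_id = "cfr"`.
#' @export
cfr_baseline_ite <- function(stage0, features, band = BAND_DEFAULT) {
  if (is.null(stage0$head_niv)) stop("untrained stage 0 heads")
  fw <- stage0_forward(stage0, features)
  new_ite_tbl(features$encounter_id, "cfr", fw$p0, fw$p1, band, 0L)
}

#' X-Learner baseline ITE
#'
#' The standard two-stage meta-learner: per-arm outcome models, imputed
#' individual effects, per-arm effect regressions, combined with propensity
#' weights `tau(x) = e(x) tau0(x) + (1 - e(x)) tau1(x)`.  The default base
#' learners are lasso-penalized logistic regressions on a second-order
#' (pairwise-interaction) design for the outcomes and lasso linear
#' regressions for the effect models and propensity, with penalties chosen by
#' seeded cross-validation (`learner = "glmnet"`); unpenalized GLM/LM base
#' learners (`"glm"`) and random forests via the ranger package (`"ranger"`)
#' are available.
#'
#' @param features `flowcfr_features` (or a plain numeric matrix).
#' @param a Treatment vector (0 = NIV, 1 = HFNC).
#' @param y Binary outcome.
#' @param learner `"glmnet"`, `"glm"` or `"ranger"`.
#' @param band Indifference half-width.
#' @param seed Seed for cross-validation folds / forests.
#' @return A `flowcfr_ite` tibble with `engine_id = "x_learner"`.
#' @export
x_learner_ite <- function(features, a, y, learner = c("glmnet", "glm", "ranger"),
                          band = BAND_DEFAULT, seed = 1L) {
  learner <- match.arg(learner)
  X <- if (inherits(features, "flowcfr_features")) features$x else as.matrix(features)
  ids <- if (inherits(features, "flowcfr_features")) {
    features$encounter_id
  } else {
    seq_len(nrow(X))
  }
  a <- as.integer(a); y <- as.integer(y)
  if (length(unique(a)) < 2L) stop("x_learner_ite: both arms required")
  set.seed(seed)
  i0 <- a == 0L; i1 <- a == 1L

  if (learner == "glmnet") {
    X2 <- pairwise_expand(X)
    fold <- function(n) sample(rep(1:5, length.out = n))
    cvfit <- function(Z, t, rows, fam = "gaussian") {
      glmnet::cv.glmnet(Z[rows, , drop = FALSE], t[rows], family = fam,
                        foldid = fold(sum(rows)))
    }
    prd <- function(m, Z, type = "link") {
      drop(predict(m, Z, s = "lambda.min", type = type))
    }
    m0 <- cvfit(X2, y, i0, "binomial"); m1 <- cvfit(X2, y, i1, "binomial")
    mu0 <- prd(m0, X2, "response"); mu1 <- prd(m1, X2, "response")
    d1 <- y[i1] - mu0[i1]; d0 <- mu1[i0] - y[i0]
    dd <- numeric(length(a)); dd[i1] <- d1; dd[i0] <- d0
    t1 <- cvfit(X, dd, i1); t0 <- cvfit(X, dd, i0)
    tau1 <- prd(t1, X); tau0 <- prd(t0, X)
    e <- prd(cvfit(X, a, rep(TRUE, length(a)), "binomial"), X, "response")
  } else if (learner == "glm") {
    df <- as.data.frame(X)
    names(df) <- make.names(colnames(X) %||% paste0("f", seq_len(ncol(X))),
                            unique = TRUE)
    fit_out <- function(rows) {
      glm(y ~ ., data = cbind(df[rows, , drop = FALSE], y = y[rows]),
          family = binomial())
    }
    m0 <- fit_out(i0); m1 <- fit_out(i1)
    mu0 <- predict(m0, newdata = df, type = "response")
    mu1 <- predict(m1, newdata = df, type = "response")
    d1 <- y[i1] - mu0[i1]             # imputed effect on the treated
    d0 <- mu1[i0] - y[i0]             # imputed effect on the controls
    t1 <- lm(d ~ ., data = cbind(df[i1, , drop = FALSE], d = d1))
    t0 <- lm(d ~ ., data = cbind(df[i0, , drop = FALSE], d = d0))
    tau1 <- predict(t1, newdata = df)
    tau0 <- predict(t0, newdata = df)
    ps <- glm(a ~ ., data = cbind(df, a = a), family = binomial())
    e <- predict(ps, newdata = df, type = "response")
  } else {
    if (!requireNamespace("ranger", quietly = TRUE)) {
      stop("learner = 'ranger' requires the ranger package")
    }
    df <- as.data.frame(X)
    names(df) <- make.names(colnames(X) %||% paste0("f", seq_len(ncol(X))),
                            unique = TRUE)
    rf <- function(target, rows, prob = FALSE) {
      dat <- cbind(df[rows, , drop = FALSE],
                   .t = if (prob) factor(target[rows]) else target[rows])
      ranger::ranger(.t ~ ., data = dat, num.trees = 300, probability = prob,
                     seed = seed)
    }
    pr <- function(m, prob = FALSE) {
      p <- predict(m, data = df)$predictions
      if (prob) p[, "1"] else p
    }
    m0 <- rf(y, i0, prob = TRUE); m1 <- rf(y, i1, prob = TRUE)
    mu0 <- pr(m0, TRUE); mu1 <- pr(m1, TRUE)
    dd <- numeric(length(a))
    dd[i1] <- y[i1] - mu0[i1]; dd[i0] <- mu1[i0] - y[i0]
    t1 <- rf(dd, i1); t0 <- rf(dd, i0)
    tau1 <- pr(t1); tau0 <- pr(t0)
    psm <- rf(a, rep(TRUE, length(a)), prob = TRUE)
    e <- pr(psm, TRUE)
  }

  tau <- e * tau0 + (1 - e) * tau1    # effect of HFNC on event probability
  p_niv <- pmin(pmax(mu0, 0), 1)
  p_hfnc <- pmin(pmax(mu0 + tau, 0), 1)
  new_ite_tbl(ids, "x_learner", p_niv, p_hfnc, band, 0L)
}

# columns of X plus all pairwise products (second-order design)
pairwise_expand <- function(X) {
  p <- ncol(X)
  if (p < 2) return(X)
  prods <- lapply(seq_len(p - 1), function(i) {
    X[, (i + 1):p, drop = FALSE] * X[, i]
  })
  cbind(X, do.call(cbind, prods))
}

#' Causal Forest adapter
#'
#' Thin adapter around the grf package's causal forest, normalising its output
#' into the common ITE schema.  When grf is not installed the adapter returns
#' a structured skip object (class `flowcfr_skipped`) carrying a diagnostic
#' message rather than failing silently.
#'
#' @inheritParams x_learner_ite
#' @param num_trees Number of trees for the forest.
#' @return A `flowcfr_ite` tibble with `engine_id = "causal_forest"`, or a
#'   `flowcfr_skipped` object when the backend is unavailable.
#' @export
causal_forest_ite <- function(features, a, y, band = BAND_DEFAULT,
                              num_trees = 1000, seed = 1L) {
  if (!requireNamespace("grf", quietly = TRUE)) {
    return(structure(
      list(engine_id = "causal_forest",
           reason = "backend package 'grf' is not installed"),
      class = "flowcfr_skipped"))
  }
  X <- if (inherits(features, "flowcfr_features")) features$x else as.matrix(features)
  ids <- if (inherits(features, "flowcfr_features")) features$encounter_id else seq_len(nrow(X))
  cf <- grf::causal_forest(X, as.numeric(y), as.numeric(a),
                           num.trees = num_trees, seed = seed)
  tau <- predict(cf)$predictions       # effect of HFNC
  mu0 <- pmin(pmax(cf$Y.hat - cf$W.hat * tau, 0), 1)
  p_hfnc <- pmin(pmax(mu0 + tau, 0), 1)
  new_ite_tbl(ids, "causal_forest", mu0, p_hfnc, band, 0L)
}

#' @export
print.flowcfr_skipped <- function(x, ...) {
  cat(sprintf("<engine %s skipped: %s>\n", x$engine_id, x$reason))
  invisible(x)
}

#' Write an ITE table as delimited text
#'
#' @param ite A `flowcfr_ite` tibble.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ite <- function(ite, path) {
  readr::write_csv(ite, path)
  invisible(path)
}
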
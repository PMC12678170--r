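# Representation learner: gate, encoder, loss, balancing behaviour.

fake_features <- function(X, tslm = NULL, n_channels = 0) {
  flowcfr:::new_features(
    X, tslm %||% matrix(0, nrow(X), n_channels), NULL,
    channels = if (n_channels > 0) paste0("c", seq_len(n_channels)) else character(0),
    statics = character(0), scaler = NULL, encounter_id = seq_len(nrow(X)))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("fresh data passes the gate unchanged; stale data attenuates to 0", {
  set.seed(1)
  X <- matrix(rnorm(5 * 8), 5)   # 2 channels x 4 blocks
  f_fresh <- fake_features(X, matrix(0, 5, 2), 2)
  expect_equal(tslm_gate(f_fresh, c(0.5, 0.5)), X)

  f_stale <- fake_features(X, matrix(1e6, 5, 2), 2)
  gated <- tslm_gate(f_stale, c(0.5, 0.5))
  expect_equal(gated[, 1:6], matrix(0, 5, 6), ignore_attr = TRUE)
  expect_equal(gated[, 7:8], X[, 7:8])        # tslm block passes through

  # intermediate staleness matches the closed form
  f_mid <- fake_features(X, matrix(3, 5, 2), 2)
  w <- c(-1, 2)
  g <- exp(-log1p(exp(w)) * 3)
  expect_equal(tslm_gate(f_mid, w)[, 1], X[, 1] * g[1])
  expect_equal(tslm_gate(f_mid, w)[, 2], X[, 2] * g[2])

  f_neg <- fake_features(X, matrix(-1, 5, 2), 2)
  expect_error(tslm_gate(f_neg), "negative tslm")
})

test_that("encoding is deterministic, permutation-equivariant, and bias-only at zero weights", {
  set.seed(2)
  X <- matrix(rnorm(40), 10)
  f <- fake_features(X)
  p <- flowcfr:::stage0_new(4, 0, hidden = 6, rep_dim = 3)
  phi1 <- encode(p, f)
  expect_identical(phi1, encode(p, f))
  expect_identical(phi1[c(3, 3), ], encode(p, fake_features(X[c(3, 3), ]))[1:2, ])
  perm <- sample(10)
  expect_equal(encode(p, fake_features(X[perm, ])), phi1[perm, ])

  p0 <- p; p0$W1[] <- 0; p0$W2[] <- 0; p0$b2 <- c(1, -2, 3)
  expect_equal(encode(p0, f), matrix(rep(c(1, -2, 3), each = 10), 10),
               ignore_attr = TRUE)
  expect_error(encode(p, fake_features(matrix(0, 2, 9))), "dimension")
})

test_that("stage 0 loss reduces to hand-computed cross-entropy plus exact W1", {
  set.seed(3)
  X <- matrix(rnorm(16), 4)
  f <- fake_features(X)
  p <- flowcfr:::stage0_new(4, 0, hidden = 4, rep_dim = 2)
  p$head_niv$w <- c(0.5, -0.3); p$head_hfnc$w <- c(-0.2, 0.4)
  a <- c(0L, 1L, 0L, 1L); y <- c(1L, 0L, 0L, 1L)

  fw <- flowcfr:::stage0_forward(p, f)
  p_fact <- ifelse(a == 1, fw$p1, fw$p0)
  bce_hand <- -mean(y * log(p_fact + 1e-12) + (1 - y) * log(1 - p_fact + 1e-12))
  w1_hand <- ipm_distance(fw$phi[a == 0, ], fw$phi[a == 1, ])

  expect_equal(as.numeric(stage0_loss(p, f, a, y, lambda = 0)), bce_hand,
               tolerance = 1e-10)
  expect_equal(as.numeric(stage0_loss(p, f, a, y, lambda = 2)),
               bce_hand + 2 * w1_hand, tolerance = 1e-10)
  expect_error(stage0_loss(p, f, rep(1L, 4), y, lambda = 1), "both arms")
})

test_that("stage 0 gradients match finite differences", {
  set.seed(4)
  X <- matrix(rnorm(8 * 8), 8)
  tslm <- matrix(abs(rnorm(8 * 2)), 8)
  f <- fake_features(X, tslm, 2)
  p <- flowcfr:::stage0_new(8, 2, hidden = 5, rep_dim = 2)
  p$head_niv$w <- rnorm(2); p$head_hfnc$w <- rnorm(2)
  a <- rep(c(0L, 1L), 4); y <- rep(c(1L, 0L), each = 4)
  res <- flowcfr:::stage0_loss_grad(p, f, a, y, lambda = 0.5)
  eps <- 1e-6
  flat <- flowcfr:::stage0_get_params(p)
  for (nm in names(flat)) {
    v <- flat[[nm]]
    for (i in seq_len(min(length(v), 4))) {
      up <- flat; up[[nm]][i] <- v[i] + eps
      dn <- flat; dn[[nm]][i] <- v[i] - eps
      lu <- flowcfr:::stage0_loss_grad(flowcfr:::stage0_set_params(p, up),
                                       f, a, y, 0.5, grad = FALSE)$loss
      ld <- flowcfr:::stage0_loss_grad(flowcfr:::stage0_set_params(p, dn),
                                       f, a, y, 0.5, grad = FALSE)$loss
      expect_equal(as.numeric(res$grads[[nm]])[i], (lu - ld) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("stronger balancing weights give non-increasing representation imbalance", {
  sc <- small_cohort(n = 400, gamma = 1.5, seed = 77)
  feats <- features_from_cohort(sc$cohort)
  a <- sc$cohort$a; y <- sc$cohort$y
  final_ipm <- function(lambda, seed) {
    set.seed(seed)
    cfg <- repflow_config(epochs = 12L, patience = 12L, batch_size = 64L,
                          hidden = 16L, rep_dim = 4L, lambda = lambda)
    s0 <- flowcfr:::train_stage0(feats, a, y, cfg, val_idx = 1:80)
    phi <- encode(s0$params, feats)
    ipm_distance(phi[a == 0, ], phi[a == 1, ])
  }
  meds <- vapply(c(0, 0.1, 1, 10), function(l) {
    median(vapply(1:5, function(s) final_ipm(l, s), numeric(1)))
  }, numeric(1))
  # non-increasing up to the finite-sample floor of the exact W1 between
  # same-distribution samples (~0.01 here): allow that much slack per step
  expect_true(all(diff(meds) <= 0.01))
  expect_lt(meds[4], 0.1 * meds[1])     # and the penalty bites hard overall
})
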
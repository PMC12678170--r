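# Preprocessing rules: binning, carry-forward expiry, imputation, derived
# features.  The 24-h boundary cases are pinned exactly.

mk_record <- function(times, values, channel = "hr") {
  tibble::tibble(channel = channel, time_hours = times, value = values)
}

test_that("hourly binning takes the median within each hour", {
  rec <- mk_record(c(0.1, 0.5, 0.9), c(3, 5, 100))
  g <- bin_hourly(rec)
  expect_equal(g$value[g$hour == 0], 5)
  # one value per bin passes through unchanged
  rec2 <- mk_record(c(0.2, 1.7, 2.3), c(10, 20, 30))
  g2 <- bin_hourly(rec2)
  expect_equal(g2$value, c(10, 20, 30))
  expect_true(all(g2$observed))
})

test_that("binning agrees with a naive sort-and-middle oracle on random streams", {
  set.seed(12)
  for (r in 1:10) {
    n <- 60
    rec <- mk_record(runif(n, 0, 12), rnorm(n))
    g <- bin_hourly(rec, n_hours = 12)
    for (h in 0:11) {
      vals <- rec$value[rec$time_hours >= h & rec$time_hours < h + 1]
      oracle <- if (length(vals) == 0) NA_real_ else {
        sv <- sort(vals); m <- length(sv)
        if (m %% 2 == 1) sv[(m + 1) / 2] else (sv[m / 2] + sv[m / 2 + 1]) / 2
      }
      expect_equal(g$value[g$hour == h], oracle)
    }
  }
})

test_that("carry-forward is inclusive at exactly 24 h and expires after", {
  rec <- mk_record(0.5, 42)
  g24 <- bin_hourly(rec, n_hours = 25)
  f24 <- carry_forward(g24)
  expect_equal(f24$value[f24$hour == 24], 42)   # age exactly 24: carried
  expect_equal(f24$tslm[f24$hour == 24], 24)
  g25 <- bin_hourly(rec, n_hours = 26)
  f25 <- carry_forward(g25)
  expect_true(is.na(f25$value[f25$hour == 25])) # age 25: expired
  # fully observed grid is unchanged with tslm 0
  rec2 <- mk_record(0:5 + 0.5, 1:6)
  f2 <- carry_forward(bin_hourly(rec2))
  expect_equal(f2$value, 1:6)
  expect_true(all(f2$tslm == 0))
})

test_that("mean imputation fills remaining gaps from training means only", {
  grid <- dplyr::bind_rows(
    mk_record(c(0.5), c(10)) |> bin_hourly(n_hours = 3),
    mk_record(numeric(0), numeric(0), channel = "bp") |>
      (\(r) tibble::tibble(channel = "bp", hour = 0:2, value = NA_real_,
                           observed = FALSE))()
  )
  means <- c(hr = 99, bp = 120)
  out <- mean_impute(carry_forward(grid), means)
  expect_false(any(is.na(out$value)))
  expect_true(all(out$value[out$channel == "bp"] == 120))
  expect_equal(out$imputed, is.na(carry_forward(grid)$value))
  expect_error(mean_impute(grid, c(hr = 99)), "bp")
  # no missing cells: identity
  full <- carry_forward(bin_hourly(mk_record(0:2 + 0.5, c(1, 2, 3))))
  expect_equal(mean_impute(full, c(hr = 50))$value, c(1, 2, 3))
})

test_that("derived features follow the stated definitions", {
  # constant channel: baseline equals the constant, slope 0
  recc <- mk_record(0:9 + 0.5, rep(7, 10))
  fc <- derive_features(bin_hourly(recc), 9)
  expect_equal(fc$baseline_72h, 7)
  expect_equal(fc$delta, 0)
  expect_equal(fc$tslm, 0)

  # observations at t0-2 (v=10) and t0 (v=16): slope 3 per hour
  rec <- mk_record(c(8.5, 10.5), c(10, 16))
  f <- derive_features(bin_hourly(rec, n_hours = 11), 10)
  expect_equal(f$delta, 3)

  # observations 30 h apart: time gap capped at 24
  rec30 <- mk_record(c(0.5, 30.5), c(0, 48))
  f30 <- derive_features(bin_hourly(rec30, n_hours = 31), 30)
  expect_equal(f30$delta, 48 / 24)

  # fewer than two observations: slope falls back to 0
  rec1 <- mk_record(2.5, 5)
  f1 <- derive_features(bin_hourly(rec1, n_hours = 10), 9)
  expect_equal(f1$delta, 0)
  expect_equal(f1$tslm, 7)      # true-observation age, beyond carry-forward

  # baseline uses only the trailing 72 h of observed values
  times <- c(0.5, 50.5, 80.5, 100.5)
  recw <- mk_record(times, c(1000, 30, 60, 90))
  fw <- derive_features(bin_hourly(recw, n_hours = 101), 100)
  expect_equal(fw$baseline_72h, mean(c(30, 60, 90)))

  expect_error(derive_features(bin_hourly(rec), -1), ">= 0")
  expect_error(derive_features(bin_hourly(rec, n_hours = 11), 50), "grid")
})

test_that("cohort feature matrices are finite, deterministic, and leak-free", {
  sc <- small_cohort(n = 25, seed = 19, ts_hours = 48, missing_rate = 0.5)
  longi <- simulate_longitudinal(sc$cohort, sc$cfg)
  train_ids <- sc$cohort$encounter_id[1:15]
  f1 <- build_features(sc$cohort, longi, train_ids = train_ids)
  f2 <- build_features(sc$cohort, longi, train_ids = train_ids)
  expect_identical(f1$x, f2$x)
  expect_true(all(is.finite(f1$x)))
  expect_true(all(f1$tslm >= 0))
  expect_equal(ncol(f1$x), 4 * length(sc$cfg$channels) + 5)

  # imputation means must depend only on the training split: recompute with a
  # different held-out set but the same training ids
  f3 <- build_features(sc$cohort[1:20, ],
                       longi[longi$encounter_id <= 20, ],
                       train_ids = train_ids)
  expect_equal(f1$scaler$channel_means, f3$scaler$channel_means)
})
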
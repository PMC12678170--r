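# Measurement-stream preprocessing.
#
# Irregular timestamped channel measurements are turned into the fixed-length
# feature vector consumed at the decision hour T0:
#   * values falling in the same hour bin are collapsed to their median;
#   * missing bins take the most recent value if it is at most 24 h old
#     (boundary inclusive), with the age recorded as time-since-last-
#     measurement (TSLM);
#   * cells still missing are filled with training-split channel means;
#   * per channel, the feature block is (current value, trailing 72-h mean of
#     observed values, short-term slope per hour between the last two true
#     observations with the time gap capped at 24 h, TSLM at T0).
# Static covariates are appended unchanged.  All statistics used for scaling
# and imputation come from the training split only.

CARRY_FORWARD_MAX_H <- 24
BASELINE_WINDOW_H <- 72
DELTA_DT_CAP_H <- 24

#' Bin a measurement stream into an hourly grid by median
#'
#' Values with timestamps in `[h, h + 1)` are collapsed to their median; hours
#' with no measurement are present in the output with `NA`.
#'
#' @param record Long tibble with columns `channel`, `time_hours`, `value`
#'   (an `encounter_id` column, if present, must be constant).
#' @param n_hours Number of hourly bins; defaults to covering the last
#'   timestamp.
#' @return Tibble `channel`, `hour` (0-based), `value`, `observed` (logical),
#'   complete over channels x hours.
#' @export
bin_hourly <- function(record, n_hours = NULL) {
  if ("encounter_id" %in% names(record) &&
      dplyr::n_distinct(record$encounter_id) > 1) {
    stop("bin_hourly operates on a single encounter")
  }
  if (is.null(n_hours)) {
    n_hours <- if (nrow(record) == 0) 1L else floor(max(record$time_hours)) + 1L
  }
  chans <- unique(record$channel)
  if (length(chans) == 0L) {
    return(tibble::tibble(channel = character(), hour = integer(),
                          value = double(), observed = logical()))
  }
  binned <- record |>
    dplyr::mutate(hour = as.integer(floor(.data$time_hours))) |>
    dplyr::group_by(.data$channel, .data$hour) |>
    dplyr::summarise(value = stats::median(.data$value), .groups = "drop")
  grid <- tidyr::expand_grid(channel = chans, hour = 0:(n_hours - 1L))
  grid |>
    dplyr::left_join(binned, by = c("channel", "hour")) |>
    dplyr::mutate(observed = !is.na(.data$value)) |>
    dplyr::arrange(.data$channel, .data$hour)
}

#' Carry observations forward for up to 24 hours
#'
#' Missing cells take the most recent observed value of the same channel when
#' its age is at most `max_hours` (inclusive at the boundary); older values
#' expire and the cell stays missing.  The age in hours of the value backing
#' each cell is recorded as `tslm` (0 for freshly observed cells; `NA` where
#' no value is available).
#'
#' @param grid Hourly grid from [bin_hourly()].
#' @param max_hours Maximum carry-forward age in hours.
#' @return The grid with `value` filled where allowed and a `tslm` column.
#' @export
carry_forward <- function(grid, max_hours = CARRY_FORWARD_MAX_H) {
  grid |>
    dplyr::group_by(.data$channel) |>
    dplyr::arrange(.data$hour, .by_group = TRUE) |>
    dplyr::mutate(
      last_obs_hour = cummax_na(ifelse(.data$observed, .data$hour, NA_real_)),
      tslm = .data$hour - .data$last_obs_hour,
      value = dplyr::if_else(
        !.data$observed & !is.na(.data$tslm) & .data$tslm <= max_hours,
        fill_forward(.data$value),
        .data$value
      ),
      tslm = dplyr::if_else(is.na(.data$value), NA_real_, .data$tslm)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"last_obs_hour")
}

# running maximum ignoring NA (NA until the first observation)
cummax_na <- function(x) {
  out <- x
  cur <- NA_real_
  for (i in seq_along(x)) {
    if (!is.na(x[i])) cur <- max(cur, x[i], na.rm = TRUE)
    out[i] <- cur
  }
  out
}

# last-observation-carried-forward on values (no age limit; limited by caller)
fill_forward <- function(v) {
  out <- v
  cur <- NA_real_
  for (i in seq_along(v)) {
    if (!is.na(v[i])) cur <- v[i]
    out[i] <- cur
  }
  out
}

#' Fill remaining missing cells with training-split channel means
#'
#' @param grid Grid from [carry_forward()] (or [bin_hourly()]).
#' @param training_means Named numeric vector of per-channel means computed on
#'   the training split; every channel in `grid` must be present.
#' @return The grid with no missing values and an `imputed` indicator column.
#' @export
mean_impute <- function(grid, training_means) {
  missing_ch <- setdiff(unique(grid$channel), names(training_means))
  if (length(missing_ch) > 0) {
    stop("mean_impute: channels absent from training_means: ",
         paste(missing_ch, collapse = ", "))
  }
  grid |>
    dplyr::mutate(
      imputed = is.na(.data$value),
      value = dplyr::if_else(is.na(.data$value),
                             unname(training_means[.data$channel]),
                             .data$value)
    )
}

#' Derive the per-channel feature block at the decision hour
#'
#' For each channel at hour `t0_hour`: the current (carried-forward) value,
#' the mean of truly observed values in the window `(t0 - 72, t0]` hours, the
#' short-term slope per hour between the last two true observations at or
#' before `t0` (time gap capped at 24 h; 0 when fewer than two observations),
#' and the time since the last true observation (TSLM, `NA`-free: hours since
#' start when never observed).
#'
#' @param grid Hourly grid from [bin_hourly()] (pre-imputation: the baseline
#'   and slope use observed values only).
#' @param t0_hour Decision hour (0-based, within the grid).
#' @return Tibble with one row per channel: `channel`, `raw_t0`,
#'   `baseline_72h`, `delta`, `tslm`, `observed_t0`.  `raw_t0`,
#'   `baseline_72h` are `NA` for never-observed channels (filled downstream by
#'   imputation).
#' @export
derive_features <- function(grid, t0_hour) {
  if (t0_hour < 0) stop("t0_hour must be >= 0")
  if (t0_hour > max(grid$hour)) stop("t0_hour outside the grid")
  cf <- carry_forward(grid)
  cf_t0 <- cf[cf$hour == t0_hour, ]
  obs <- grid[grid$observed, ]
  per_channel <- function(ch) {
    o <- obs[obs$channel == ch & obs$hour <= t0_hour, ]
    o <- o[order(o$hour), ]
    in_win <- o[o$hour > t0_hour - BASELINE_WINDOW_H, ]
    baseline <- if (nrow(in_win) > 0) mean(in_win$value) else NA_real_
    if (nrow(o) >= 2) {
      k <- nrow(o)
      dt <- min(o$hour[k] - o$hour[k - 1L], DELTA_DT_CAP_H)
      delta <- (o$value[k] - o$value[k - 1L]) / dt
    } else {
      delta <- 0
    }
    tslm <- if (nrow(o) > 0) t0_hour - max(o$hour) else t0_hour + 1
    tibble::tibble(channel = ch, baseline_72h = baseline, delta = delta,
                   tslm = as.numeric(tslm))
  }
  feats <- purrr::map_dfr(unique(grid$channel), per_channel)
  raw <- cf_t0[, c("channel", "value")]
  names(raw)[2] <- "raw_t0"
  out <- dplyr::left_join(feats, raw, by = "channel")
  out$observed_t0 <- !is.na(out$raw_t0)
  out[, c("channel", "raw_t0", "baseline_72h", "delta", "tslm", "observed_t0")]
}

#' Build the model feature matrix for a cohort
#'
#' Applies the full preprocessing chain per encounter (hourly median binning,
#' carry-forward, feature derivation at each encounter's `t0_hour`, mean
#' imputation with training-split channel statistics) and appends the static
#' adjuster block.  All columns are z-scored with training-split statistics;
#' the raw per-channel TSLM matrix is kept alongside for the staleness gate.
#'
#' @param cohort Cohort tibble (needs `encounter_id`, `t0_hour` and the static
#'   columns).
#' @param longitudinal Long measurement tibble covering the cohort.
#' @param statics Character vector of static column names to append.
#' @param train_ids Encounter ids of the training split; imputation means and
#'   scaling statistics are computed from these rows only (default: all).
#' @return A `flowcfr_features` object: list with `x` (standardized matrix),
#'   `tslm` (raw per-channel staleness matrix), `mask` (imputed indicator),
#'   `channels`, `statics`, `scaler`, `encounter_id`.
#' @export
build_features <- function(cohort, longitudinal, statics = c("age", "sex",
                           "sofa_t0", "cci", "risk_t0"),
                           train_ids = cohort$encounter_id) {
  chans <- sort(unique(longitudinal$channel))
  rows <- purrr::map(cohort$encounter_id, function(id) {
    rec <- longitudinal[longitudinal$encounter_id == id, ]
    t0 <- cohort$t0_hour[cohort$encounter_id == id]
    grid <- bin_hourly(rec, n_hours = max(t0 + 1L, 1L))
    missing_ch <- setdiff(chans, unique(grid$channel))
    if (length(missing_ch) > 0) {
      grid <- dplyr::bind_rows(grid, tidyr::expand_grid(
        channel = missing_ch, hour = 0:max(grid$hour %||% 0),
        value = NA_real_, observed = FALSE))
    }
    derive_features(grid, t0)
  })
  feat_long <- dplyr::bind_rows(rows, .id = "row")

  is_train <- cohort$encounter_id %in% train_ids
  train_rows <- feat_long$row %in% as.character(which(is_train))
  ch_means <- feat_long[train_rows, ] |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(raw = mean(.data$raw_t0, na.rm = TRUE),
                     baseline = mean(.data$baseline_72h, na.rm = TRUE),
                     .groups = "drop")

  feat_long <- feat_long |>
    dplyr::left_join(ch_means, by = "channel") |>
    dplyr::mutate(
      imputed = is.na(.data$raw_t0),
      raw_t0 = dplyr::if_else(is.na(.data$raw_t0), .data$raw, .data$raw_t0),
      baseline_72h = dplyr::if_else(is.na(.data$baseline_72h),
                                    .data$baseline, .data$baseline_72h)
    )

  to_wide <- function(col) {
    w <- tidyr::pivot_wider(feat_long, id_cols = "row",
                            names_from = "channel",
                            values_from = dplyr::all_of(col))
    w <- w[order(as.integer(w$row)), ]
    as.matrix(w[, chans, drop = FALSE])
  }
  raw_m <- to_wide("raw_t0")
  base_m <- to_wide("baseline_72h")
  delta_m <- to_wide("delta")
  tslm_m <- to_wide("tslm")
  mask_m <- to_wide("imputed")

  stat_m <- as.matrix(cohort[, statics, drop = FALSE])
  X <- cbind(raw_m, base_m, delta_m, tslm_m, stat_m)
  colnames(X) <- c(paste0(chans, "_raw"), paste0(chans, "_baseline"),
                   paste0(chans, "_delta"), paste0(chans, "_tslm"), statics)

  mu <- colMeans(X[is_train, , drop = FALSE])
  sdv <- apply(X[is_train, , drop = FALSE], 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  if (!all(is.finite(Xs))) stop("non-finite values in feature matrix")

  new_features(Xs, tslm_m, mask_m, chans, statics,
               scaler = list(mu = mu, sd = sdv, channel_means = ch_means),
               encounter_id = cohort$encounter_id)
}

#' Build features directly from encounter-level covariates
#'
#' Bypass for cohorts analysed at the decision time only: the measured
#' covariate columns plus adjusters form the feature matrix with zero
#' staleness (every channel "freshly observed"); used for simulation studies
#' that do not exercise the longitudinal path.
#'
#' @inheritParams build_features
#' @param covariates Character vector of covariate column names (default: the
#'   `x1..xd` columns).
#' @return A `flowcfr_features` object (see [build_features()]).
#' @export
features_from_cohort <- function(cohort,
                                 covariates = grep("^x[0-9]+$", names(cohort),
                                                   value = TRUE),
                                 statics = c("age", "sex", "sofa_t0", "cci",
                                             "risk_t0"),
                                 train_ids = cohort$encounter_id) {
  X <- as.matrix(cohort[, c(covariates, statics), drop = FALSE])
  is_train <- cohort$encounter_id %in% train_ids
  mu <- colMeans(X[is_train, , drop = FALSE])
  sdv <- apply(X[is_train, , drop = FALSE], 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  tslm <- matrix(0, nrow(X), 0)
  new_features(Xs, tslm, NULL, character(0), c(covariates, statics),
               scaler = list(mu = mu, sd = sdv),
               encounter_id = cohort$encounter_id)
}

new_features <- function(x, tslm, mask, channels, statics, scaler,
                         encounter_id) {
  structure(list(x = x, tslm = tslm, mask = mask, channels = channels,
                 statics = statics, scaler = scaler,
                 encounter_id = encounter_id),
            class = "flowcfr_features")
}

#' @export
print.flowcfr_features <- function(x, ...) {
  cat(sprintf("<flowcfr_features> %d encounters, %d features (%d channels x 4 + %d statics)\n",
              nrow(x$x), ncol(x$x), length(x$channels), length(x$statics)))
  invisible(x)
}

#' @export
dim.flowcfr_features <- function(x) dim(x$x)

# subset rows of a feature object
features_subset <- function(features, idx) {
  new_features(features$x[idx, , drop = FALSE],
               features$tslm[idx, , drop = FALSE],
               if (!is.null(features$mask)) features$mask[idx, , drop = FALSE],
               features$channels, features$statics, features$scaler,
               features$encounter_id[idx])
}
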
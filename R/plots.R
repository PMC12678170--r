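# ggplot2 displays for the package's result types.

#' Grouped bar chart of outcome rates by arm and concordance
#'
#' Mirrors the standard four-group display: outcome rate for NIV-concordant,
#' NIV-discordant, HFNC-concordant and HFNC-discordant encounters.
#'
#' @param object A rate table from [outcome_rates_by_group()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flowcfr_rates
#' @export
autoplot.flowcfr_rates <- function(object, ...) {
  df <- dplyr::mutate(object,
    group = factor(paste(.data$actual,
                         ifelse(.data$concordant, "concordant", "discordant")),
                   levels = c("NIV concordant", "NIV discordant",
                              "HFNC concordant", "HFNC discordant")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$rate,
                                   fill = .data$actual)) +
    ggplot2::geom_col(width = 0.7, na.rm = TRUE) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("n=%d", .data$n)),
                       vjust = -0.4, size = 3, na.rm = TRUE) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = paste(unique(df$outcome), "rate"),
                  fill = "Initial arm") +
    ggplot2::theme_minimal()
}

#' Histogram of estimated individual treatment effects
#'
#' Shows the distribution of `ite` (risk under NIV minus risk under HFNC)
#' with the indifference band shaded.
#'
#' @param object A `flowcfr_ite` tibble.
#' @param band Indifference half-width drawn around zero.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flowcfr_ite
#' @export
autoplot.flowcfr_ite <- function(object, band = BAND_DEFAULT, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ite,
                                       fill = .data$band_label)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::geom_vline(xintercept = c(-band, band), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = "ITE  (P(IMV | NIV) - P(IMV | HFNC))", y = "encounters",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of adjusted odds ratios
#'
#' @param object A `flowcfr_logistic` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flowcfr_logistic
#' @export
autoplot.flowcfr_logistic <- function(object, ...) {
  df <- object$table[object$table$term != "(Intercept)", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio,
                                   y = stats::reorder(.data$term,
                                                      .data$odds_ratio))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Adjusted odds ratio (95% CI)", y = NULL,
                  title = paste("Outcome:", object$outcome)) +
    ggplot2::theme_minimal()
}

#' Tidy an ITE table
#'
#' Returns the estimates as a plain tibble (already tidy; provided for
#' pipeline symmetry).
#'
#' @param x A `flowcfr_ite` tibble.
#' @param ... Unused.
#' @method tidy flowcfr_ite
#' @export
tidy.flowcfr_ite <- function(x, ...) tibble::as_tibble(x)

#' Summarise an ITE table
#'
#' @param x A `flowcfr_ite` tibble.
#' @param ... Unused.
#' @return One row: engine, n, mean/SD of ite, band shares.
#' @method glance flowcfr_ite
#' @export
glance.flowcfr_ite <- function(x, ...) {
  tibble::tibble(
    engine_id = x$engine_id[1],
    n = nrow(x),
    mean_ite = mean(x$ite),
    sd_ite = sd(x$ite),
    prop_niv_preferred = mean(x$band_label == "NIV_preferred"),
    prop_hfnc_preferred = mean(x$band_label == "HFNC_preferred"),
    prop_indifferent = mean(x$band_label == "Indifferent")
  )
}

#' Tidy a fitted counterfactual model
#'
#' Per-stage validation-loss trajectories in long form.
#'
#' @param x A `repflow_model`.
#' @param ... Unused.
#' @method tidy repflow_model
#' @export
tidy.repflow_model <- function(x, ...) {
  purrr::map_dfr(names(x$history), function(st) {
    tibble::tibble(stage = st, epoch = seq_along(x$history[[st]]),
                   val_loss = x$history[[st]])
  })
}

#' Summarise a fitted counterfactual model
#'
#' @param x A `repflow_model`.
#' @param ... Unused.
#' @method glance repflow_model
#' @export
glance.repflow_model <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    rep_dim = x$config$rep_dim,
    lambda = x$config$lambda,
    flow_depth = x$config$flow_depth,
    seed = x$seed,
    stage0_val = min(x$history$stage0),
    stage1_val = min(x$history$stage1),
    stage2_val = min(x$history$stage2)
  )
}
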
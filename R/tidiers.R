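#' Tidy methods for fitted pdrisk objects
#'
#' Broom-style accessors: `tidy()` returns a one-row-per-term tibble,
#' `glance()` a one-row model summary.
#'
#' @param x A fitted pdrisk object.
#' @param ... Unused.
#' @return A tibble.
#' @name pdrisk-tidiers
NULL

#' @rdname pdrisk-tidiers
#' @export
tidy.pd_prs_selection <- function(x, ...) {
  x$table
}

#' @rdname pdrisk-tidiers
#' @export
glance.pd_prs_selection <- function(x, ...) {
  tibble::tibble(
    p_threshold = x$best$p_threshold,
    r2_threshold = x$best$r2_threshold,
    n_snps = x$best$n_snps,
    r2_nagelkerke = x$table$r2_nagelkerke[x$best_index]
  )
}

#' @rdname pdrisk-tidiers
#' @export
tidy.pd_prs_model <- function(x, ...) {
  x$variants
}

#' @rdname pdrisk-tidiers
#' @export
glance.pd_prs_model <- function(x, ...) {
  tibble::tibble(p_threshold = x$p_threshold, r2_threshold = x$r2_threshold,
                 n_snps = x$n_snps)
}

#' @rdname pdrisk-tidiers
#' @export
tidy.pd_interaction_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$factor1, x$factor2,
             paste0(x$factor1, ":", x$factor2)),
    estimate = c(x$beta0, x$beta_rf1, x$beta_rf2, x$beta_int)
  )
}

#' @rdname pdrisk-tidiers
#' @export
glance.pd_interaction_fit <- function(x, ...) {
  tibble::tibble(reri = reri_from_fit(x), ap = ap_from_fit(x),
                 flagged = x$flagged)
}

#' @rdname pdrisk-tidiers
#' @export
tidy.pd_ap_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$ap, reri = x$reri,
    ci_low = x$ci_low, ci_high = x$ci_high,
    n_boot = x$n_boot, n_failed = x$n_failed, flagged = x$flagged
  )
}

#' @rdname pdrisk-tidiers
#' @export
tidy.pd_mult_test <- function(x, ...) {
  tibble::tibble(estimate = x$mult_beta, std_error = x$se,
                 lrt_statistic = x$lrt_stat, p_value = x$lrt_p,
                 flagged = x$flagged)
}

#' @rdname pdrisk-tidiers
#' @export
tidy.pd_onset_fit <- function(x, ...) {
  tibble::tibble(term = "score_int", estimate = x$slope, std_error = x$se,
                 ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p)
}

#' @rdname pdrisk-tidiers
#' @export
glance.pd_onset_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, p_value = x$p, n = x$n)
}

#' Plot methods for pdrisk result tables
#'
#' `autoplot()` renders the standard figure for each result type: a forest
#' plot of odds ratios by score decile, the candidate-grid pseudo-R-squared
#' profile, attributable-proportion estimates with bootstrap CIs, or a
#' forest plot of risk-factor odds ratios.
#'
#' @param object A pdrisk result table.
#' @param ... Unused.
#' @return A ggplot object.
#' @name pdrisk-autoplot
NULL

#' @rdname pdrisk-autoplot
#' @export
autoplot.pd_decile_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$decile),
                                       y = .data$or)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "PRS decile (1 = lowest)",
                  y = "OR vs decile 1 (log scale)") +
    ggplot2::theme_minimal()
}

#' @rdname pdrisk-autoplot
#' @export
autoplot.pd_prs_selection <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$p_threshold),
                                    y = .data$r2_nagelkerke,
                                    colour = factor(.data$r2_threshold),
                                    group = factor(.data$r2_threshold))) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "p-value threshold", y = "Nagelkerke pseudo-R2",
                  colour = "clump r2") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname pdrisk-autoplot
#' @export
autoplot.pd_gxe_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = stats::reorder(.data$exposure,
                                                          .data$ap),
                                       y = .data$ap)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ap_ci_low,
                                          ymax = .data$ap_ci_high)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Attributable proportion (95% bootstrap CI)") +
    ggplot2::theme_minimal()
}

#' @rdname pdrisk-autoplot
#' @export
autoplot.pd_assoc_result <- function(object, ...) {
  dat <- object[!object$flagged & !is.na(object$or), , drop = FALSE]
  dat$label <- ifelse(is.na(dat$level), dat$exposure,
                      paste0(dat$exposure, ": ", dat$level))
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$label,
                                                       .data$or),
                                    y = .data$or)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "OR (95% CI, log scale)") +
    ggplot2::theme_minimal()
}
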
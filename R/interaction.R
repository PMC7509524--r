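#' Fit a logistic interaction model for two risk factors
#'
#' Fits `outcome ~ factor1 * factor2 + covariates` by maximum likelihood on
#' complete cases. Continuous (non-binary) factors are inverse-normal
#' transformed first when `int_transform` is set, so interaction contrasts
#' are per SD of the transformed variable.
#'
#' @param cohort Cohort tibble.
#' @param factor1,factor2 Column names of the two risk factors (binary 0/1
#'   or continuous).
#' @param outcome Binary outcome column.
#' @param covariates Confounder columns.
#' @param int_transform Inverse-normal transform continuous factors
#'   (default `TRUE`).
#' @return List of class `pd_interaction_fit`: `beta0`, `beta_rf1`,
#'   `beta_rf2`, `beta_int`, `flagged`, plus the underlying `glm` fit and
#'   the analysis data.
#' @export
fit_interaction <- function(cohort, factor1, factor2, outcome = "pd_status",
                            covariates = c("age", "sex", "townsend",
                                           "pc1", "pc2", "pc3", "pc4"),
                            int_transform = TRUE) {
  dat <- prepare_interaction_data(cohort, factor1, factor2, outcome,
                                  covariates, int_transform)
  f <- as.formula(paste(
    outcome, "~", paste(c(paste0(factor1, " * ", factor2), covariates),
                        collapse = " + ")
  ))
  res <- glm_flagged(f, dat)
  cf <- coef(res$fit)
  int_name <- paste0(factor1, ":", factor2)
  flagged <- res$flagged || anyNA(cf[c(factor1, factor2, int_name)])
  structure(
    list(beta0 = unname(cf["(Intercept)"]),
         beta_rf1 = unname(cf[factor1]),
         beta_rf2 = unname(cf[factor2]),
         beta_int = unname(cf[int_name]),
         flagged = flagged, fit = res$fit, data = dat,
         factor1 = factor1, factor2 = factor2,
         outcome = outcome, covariates = covariates),
    class = "pd_interaction_fit"
  )
}

prepare_interaction_data <- function(cohort, factor1, factor2, outcome,
                                     covariates, int_transform) {
  cols <- unique(c(outcome, covariates, factor1, factor2))
  stopifnot(all(cols %in% names(cohort)))
  dat <- cohort[complete.cases(cohort[, cols, drop = FALSE]), cols,
                drop = FALSE]
  if (int_transform) {
    for (fc in c(factor1, factor2)) {
      v <- dat[[fc]]
      if (is.numeric(v) && length(unique(v)) > 2) {
        dat[[fc]] <- inverse_normal_transform(v)
      }
    }
  }
  for (fc in c(factor1, factor2)) {
    if (length(unique(dat[[fc]])) < 2) {
      stop("factor '", fc, "' is constant in the analysis data", call. = FALSE)
    }
  }
  dat
}

#' Relative excess risk due to interaction
#'
#' `RERI = exp(b1 + b2 + b12) - exp(b1) - exp(b2) + 1` from the
#' coefficients of a logistic interaction model: the departure of the joint
#' odds ratio from additivity of the two single-exposure odds ratios. Zero
#' under additive-null, even when the multiplicative term is non-zero.
#'
#' @param fit A `pd_interaction_fit`, or a named numeric/list with
#'   `beta_rf1`, `beta_rf2`, `beta_int`.
#' @return RERI (unitless).
#' @examples
#' reri_from_fit(list(beta_rf1 = log(2), beta_rf2 = log(2), beta_int = 0)) # 1
#' @export
reri_from_fit <- function(fit) {
  b <- interaction_betas(fit)
  exp(b[1] + b[2] + b[3]) - exp(b[1]) - exp(b[2]) + 1
}

#' Attributable proportion due to interaction
#'
#' `AP = RERI / exp(b1 + b2 + b12)`: the share of disease in the doubly
#' exposed group attributable to interaction. Negative values indicate a
#' sub-additive joint effect.
#'
#' @inheritParams reri_from_fit
#' @return AP (proportion; may be negative).
#' @export
ap_from_fit <- function(fit) {
  b <- interaction_betas(fit)
  reri_from_fit(fit) / exp(b[1] + b[2] + b[3])
}

interaction_betas <- function(fit) {
  b <- if (inherits(fit, "pd_interaction_fit")) {
    c(fit$beta_rf1, fit$beta_rf2, fit$beta_int)
  } else {
    fl <- as.list(fit)
    c(fl$beta_rf1, fl$beta_rf2, fl$beta_int)
  }
  if (length(b) != 3 || any(!is.finite(b))) {
    stop("interaction fit has missing or non-finite coefficients",
         call. = FALSE)
  }
  b
}

#' Bootstrap percentile CI for the attributable proportion
#'
#' Point estimate from the full-data logistic interaction fit; per
#' replicate, individuals are resampled with replacement (the whole dataset,
#' no case/control stratification), the model refitted and AP recomputed.
#' The CI is the empirical 2.5th/97.5th percentile over converged
#' replicates. Refits run on a precomputed model matrix for speed. Results
#' are flagged unreliable when more than 10% of replicates fail.
#'
#' @inheritParams fit_interaction
#' @param n_boot Bootstrap replicates (default 5000).
#' @param seed Integer seed (deterministic CI).
#' @param max_fail_frac Failure fraction above which the result is flagged.
#' @return List of class `pd_ap_result`: `ap`, `reri`, `ci_low`, `ci_high`,
#'   `n_boot`, `n_failed`, `flagged`, `fit`.
#' @export
bootstrap_ap <- function(cohort, factor1, factor2, outcome = "pd_status",
                         covariates = c("age", "sex", "townsend",
                                        "pc1", "pc2", "pc3", "pc4"),
                         n_boot = 5000, seed = 1L, int_transform = TRUE,
                         max_fail_frac = 0.1) {
  fit <- fit_interaction(cohort, factor1, factor2, outcome, covariates,
                         int_transform)
  dat <- fit$data
  f <- as.formula(paste(
    "~", paste(c(paste0(factor1, " * ", factor2), covariates),
               collapse = " + ")
  ))
  X <- model.matrix(f, dat)
  y <- dat[[outcome]]
  int_name <- paste0(factor1, ":", factor2)
  idx_cols <- match(c(factor1, factor2, int_name), colnames(X))
  if (anyNA(idx_cols)) {
    stop("interaction design columns not found; are the factors numeric?",
         call. = FALSE)
  }
  n <- nrow(X)
  ap_boot <- rep(NA_real_, n_boot)
  withr::with_seed(child_seed(seed, 6L), {
    for (b in seq_len(n_boot)) {
      rows <- sample.int(n, n, replace = TRUE)
      rf <- tryCatch(fit_logit_mm(X[rows, , drop = FALSE], y[rows]),
                     error = function(e) NULL)
      if (is.null(rf) || !rf$converged) next
      cf <- rf$coefficients[idx_cols]
      if (anyNA(cf) || any(!is.finite(cf))) next
      ap_boot[b] <- ap_from_fit(list(beta_rf1 = cf[1], beta_rf2 = cf[2],
                                     beta_int = cf[3]))
    }
  })
  ok <- !is.na(ap_boot)
  n_failed <- sum(!ok)
  ci <- if (any(ok)) {
    quantile(ap_boot[ok], c(0.025, 0.975), names = FALSE, type = 7)
  } else c(NA_real_, NA_real_)
  structure(
    list(ap = ap_from_fit(fit), reri = reri_from_fit(fit),
         ci_low = ci[1], ci_high = ci[2],
         n_boot = n_boot, n_failed = n_failed,
         flagged = fit$flagged || n_failed > max_fail_frac * n_boot,
         fit = fit),
    class = "pd_ap_result"
  )
}

#' @export
print.pd_ap_result <- function(x, ...) {
  cat(sprintf("AP %.4f (95%% CI %.4f to %.4f), RERI %.4f, %d/%d bootstrap failures%s\n",
              x$ap, x$ci_low, x$ci_high, x$reri, x$n_failed, x$n_boot,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Multiplicative-scale interaction test
#'
#' Likelihood-ratio test of the logistic model with the interaction term
#' against the nested model without it; the interaction coefficient is the
#' multiplicative-scale effect.
#'
#' @inheritParams fit_interaction
#' @return List of class `pd_mult_test`: `mult_beta`, `se`, `lrt_stat`,
#'   `lrt_p`, `flagged`.
#' @export
multiplicative_test <- function(cohort, factor1, factor2,
                                outcome = "pd_status",
                                covariates = c("age", "sex", "townsend",
                                               "pc1", "pc2", "pc3", "pc4"),
                                int_transform = TRUE) {
  dat <- tryCatch(
    prepare_interaction_data(cohort, factor1, factor2, outcome,
                             covariates, int_transform),
    error = function(e) NULL
  )
  if (is.null(dat)) { # degenerate input (e.g. constant factor)
    return(structure(
      list(mult_beta = NA_real_, se = NA_real_, lrt_stat = NA_real_,
           lrt_p = NA_real_, flagged = TRUE),
      class = "pd_mult_test"
    ))
  }
  f_full <- as.formula(paste(
    outcome, "~", paste(c(paste0(factor1, " * ", factor2), covariates),
                        collapse = " + ")
  ))
  f_null <- as.formula(paste(
    outcome, "~", paste(c(factor1, factor2, covariates), collapse = " + ")
  ))
  full <- glm_flagged(f_full, dat)
  null <- glm_flagged(f_null, dat)
  int_name <- paste0(factor1, ":", factor2)
  cf <- summary(full$fit)$coefficients
  flagged <- full$flagged || null$flagged ||
    !(int_name %in% rownames(cf)) || is.na(coef(full$fit)[int_name])
  lr <- lrt(full$fit, null$fit)
  structure(
    list(mult_beta = if (int_name %in% rownames(cf)) cf[int_name, 1] else NA_real_,
         se = if (int_name %in% rownames(cf)) cf[int_name, 2] else NA_real_,
         lrt_stat = lr$statistic, lrt_p = lr$p, flagged = flagged),
    class = "pd_mult_test"
  )
}

#' Scan a family of exposures for interaction with a score
#'
#' For each exposure, computes the additive-scale statistics (RERI, AP,
#' percentile bootstrap CI) and the multiplicative-scale interaction test,
#' then adjusts the multiplicative LRT p-values across the family by
#' Benjamini-Hochberg.
#'
#' @param cohort Cohort tibble (with the score joined in).
#' @param exposures Exposure columns to test against the score.
#' @param score_col Score column name (continuous; inverse-normal
#'   transformed internally).
#' @param outcome,covariates,n_boot,seed As in [bootstrap_ap()].
#' @return Tibble of class `pd_gxe_table`: `exposure`, `reri`, `ap`,
#'   `ap_ci_low`, `ap_ci_high`, `mult_beta`, `lrt_p`, `q`, `n_boot`,
#'   `n_failed`, `flagged`.
#' @export
gxe_scan <- function(cohort, exposures, score_col = "score_int",
                     outcome = "pd_status",
                     covariates = c("age", "sex", "townsend",
                                    "pc1", "pc2", "pc3", "pc4"),
                     n_boot = 5000, seed = 1L) {
  rows <- purrr::imap(exposures, function(e, k) {
    ar <- bootstrap_ap(cohort, e, score_col, outcome, covariates,
                       n_boot = n_boot, seed = child_seed(seed, 10L + k))
    mt <- multiplicative_test(cohort, e, score_col, outcome, covariates)
    tibble::tibble(
      exposure = e, reri = ar$reri, ap = ar$ap,
      ap_ci_low = ar$ci_low, ap_ci_high = ar$ci_high,
      mult_beta = mt$mult_beta, lrt_p = mt$lrt_p,
      n_boot = ar$n_boot, n_failed = ar$n_failed,
      flagged = ar$flagged | mt$flagged
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q <- fdr_adjust(out$lrt_p)$q
  out <- out[, c("exposure", "reri", "ap", "ap_ci_low", "ap_ci_high",
                 "mult_beta", "lrt_p", "q", "n_boot", "n_failed", "flagged")]
  class(out) <- c("pd_gxe_table", class(out))
  out
}
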
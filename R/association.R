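#' Restrict a cohort to incident cases and non-cases
#'
#' Incident case-control analyses use incident cases and all participants
#' without a diagnosis as unmatched controls; prevalent cases (diagnosed
#' before baseline) are excluded.
#'
#' @param cohort Cohort tibble with `pd_status` and `incident` columns.
#' @return Filtered tibble.
#' @export
incident_subset <- function(cohort) {
  cohort[!(cohort$pd_status == 1 & cohort$incident == 0), , drop = FALSE]
}

glm_flagged <- function(formula, data) {
  flagged <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) flagged <- TRUE
  # separation heuristic: a finite-MLE log-OR beyond +/-15 is not credible
  if (any(abs(coef(fit)) > 15, na.rm = TRUE)) flagged <- TRUE
  list(fit = fit, flagged = flagged)
}

#' Adjusted logistic model for one risk factor
#'
#' Fits `outcome ~ covariates + exposure` by maximum likelihood on complete
#' cases and reports the exposure odds ratio with Wald 95% CI, the Wald
#' p-value, and the likelihood-ratio test against the covariate-only model.
#' Categorical exposures yield one row per non-reference level sharing the
#' exposure-wide LRT p. For sex-specific exposures set
#' `drop_sex_for_sex_specific` so sex is removed from the covariates.
#' Degenerate exposures (constant) and separation/non-convergence are
#' flagged, not silently dropped.
#'
#' @param cohort Cohort tibble (typically [incident_subset()] output).
#' @param exposure Exposure column name.
#' @param outcome Outcome column name (binary 0/1).
#' @param covariates Adjustment covariates.
#' @param drop_sex_for_sex_specific Remove `sex` from covariates.
#' @return Tibble of class `pd_assoc_result`: `exposure`, `level`, `or`,
#'   `ci_low`, `ci_high`, `p_wald`, `lrt_p`, `flagged`. The fitted models are
#'   attached as attributes `fit_full` / `fit_null`.
#' @export
fit_exposure_model <- function(cohort, exposure, outcome = "pd_status",
                               covariates = c("age", "sex", "ethnicity",
                                              "townsend"),
                               drop_sex_for_sex_specific = FALSE) {
  stopifnot(exposure %in% names(cohort), outcome %in% names(cohort))
  if (exposure %in% covariates) {
    stop("exposure must not be among the covariates", call. = FALSE)
  }
  if (drop_sex_for_sex_specific) covariates <- setdiff(covariates, "sex")
  covariates <- covariates[vapply(covariates, function(cl)
    length(unique(cohort[[cl]][!is.na(cohort[[cl]])])) > 1, TRUE)]
  cols <- unique(c(outcome, covariates, exposure))
  dat <- cohort[complete.cases(cohort[, cols, drop = FALSE]), cols,
                drop = FALSE]
  flag_row <- function(msg) {
    out <- tibble::tibble(exposure = exposure, level = NA_character_,
                          or = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p_wald = NA_real_,
                          lrt_p = NA_real_, flagged = TRUE)
    attr(out, "flag_reason") <- msg
    class(out) <- c("pd_assoc_result", class(out))
    out
  }
  ex <- dat[[exposure]]
  if (length(unique(ex)) < 2) return(flag_row("degenerate exposure"))
  f_full <- as.formula(paste(outcome, "~",
                             paste(c(covariates, exposure), collapse = " + ")))
  f_null <- if (length(covariates)) {
    as.formula(paste(outcome, "~", paste(covariates, collapse = " + ")))
  } else as.formula(paste(outcome, "~ 1"))
  full <- glm_flagged(f_full, dat)
  null <- glm_flagged(f_null, dat)
  cf <- summary(full$fit)$coefficients
  rows <- grep(paste0("^", exposure), rownames(cf), value = TRUE)
  if (!length(rows) || anyNA(coef(full$fit)[rows])) {
    return(flag_row("exposure coefficient undefined"))
  }
  lr <- lrt(full$fit, null$fit)
  est <- cf[rows, 1]; se <- cf[rows, 2]
  ci <- or_ci(est, se)
  lev <- sub(paste0("^", exposure), "", rows)
  lev[lev == ""] <- NA_character_
  out <- tibble::tibble(
    exposure = exposure, level = lev,
    or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high,
    p_wald = cf[rows, 4], lrt_p = lr$p,
    flagged = full$flagged
  )
  if (full$flagged) {
    out$ci_low <- NA_real_
    out$ci_high <- NA_real_
  }
  attr(out, "fit_full") <- full$fit
  attr(out, "fit_null") <- null$fit
  class(out) <- c("pd_assoc_result", class(out))
  out
}

#' Likelihood-ratio test of nested logistic models
#'
#' @param full,null Fitted `glm` objects; `null` must be nested in `full`
#'   (its terms a subset of the full model's, fitted on the same number of
#'   observations).
#' @return List: `statistic` (`2 * (ll_full - ll_null)`), `df`, `p`.
#' @export
lrt <- function(full, null) {
  t_full <- attr(terms(full), "term.labels")
  t_null <- attr(terms(null), "term.labels")
  if (!all(t_null %in% t_full) || nobs(full) != nobs(null)) {
    stop("models are not nested", call. = FALSE)
  }
  stat <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
  df <- length(coef(full)) - length(coef(null))
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up q-values with discovery flags at the given level.
#'
#' @param p P-values in (0, 1].
#' @param q_level Discovery threshold (default 0.05).
#' @return Tibble: `p`, `q`, `discovery`.
#' @export
fdr_adjust <- function(p, q_level = 0.05) {
  stopifnot(is.numeric(p), all(is.na(p) | (p > 0 & p <= 1)))
  q <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, discovery = !is.na(q) & q < q_level)
}

#' Screen a panel of risk factors with FDR control
#'
#' Runs [fit_exposure_model()] for each exposure, collects per-exposure
#' likelihood-ratio p-values, and attaches Benjamini-Hochberg q-values
#' across the family.
#'
#' @param cohort Cohort tibble.
#' @param exposures Character vector of exposure columns.
#' @param outcome,covariates Passed through to [fit_exposure_model()].
#' @param sex_specific Exposures for which sex is dropped from covariates.
#' @param q_level FDR discovery threshold.
#' @return Tibble of class `pd_assoc_result` with added `lrt_q` and
#'   `discovery` columns.
#' @export
screen_exposures <- function(cohort, exposures, outcome = "pd_status",
                             covariates = c("age", "sex", "ethnicity",
                                            "townsend"),
                             sex_specific = character(), q_level = 0.05) {
  res <- purrr::map(exposures, function(e) {
    fit_exposure_model(cohort, e, outcome, covariates,
                       drop_sex_for_sex_specific = e %in% sex_specific)
  })
  tab <- dplyr::bind_rows(res)
  fam <- tab |>
    dplyr::distinct(.data$exposure, .data$lrt_p)
  adj <- fdr_adjust(fam$lrt_p, q_level)
  fam$lrt_q <- adj$q
  fam$discovery <- adj$discovery
  out <- dplyr::left_join(tab, fam[, c("exposure", "lrt_q", "discovery")],
                          by = "exposure")
  class(out) <- c("pd_assoc_result", class(out))
  out
}

#' Combined multivariable model over selected risk factors
#'
#' One joint logistic fit containing every supplied exposure plus the
#' covariates; reports per-exposure OR, Wald CI and p. Sex-limited exposures
#' should be excluded by the caller when both sexes are analysed.
#' Coefficients dropped by aliasing (perfect collinearity) are flagged.
#'
#' @param cohort Cohort tibble.
#' @param exposures Exposure columns to include jointly (for instance those
#'   with `lrt_q < 0.05` from [screen_exposures()]).
#' @param outcome,covariates As in [fit_exposure_model()].
#' @return Tibble of class `pd_assoc_result`; fitted model in attribute
#'   `fit_full`.
#' @export
fit_combined_model <- function(cohort, exposures, outcome = "pd_status",
                               covariates = c("age", "sex", "ethnicity",
                                              "townsend")) {
  stopifnot(length(exposures) >= 1)
  covariates <- covariates[vapply(covariates, function(cl)
    length(unique(cohort[[cl]][!is.na(cohort[[cl]])])) > 1, TRUE)]
  cols <- unique(c(outcome, covariates, exposures))
  dat <- cohort[complete.cases(cohort[, cols, drop = FALSE]), cols,
                drop = FALSE]
  f <- as.formula(paste(outcome, "~",
                        paste(c(covariates, exposures), collapse = " + ")))
  full <- glm_flagged(f, dat)
  cf <- summary(full$fit)$coefficients
  aliased <- names(coef(full$fit))[is.na(coef(full$fit))]
  rows_all <- lapply(exposures, function(e) {
    rows <- grep(paste0("^", e), names(coef(full$fit)), value = TRUE)
    rows <- setdiff(rows, unlist(lapply(setdiff(exposures, e), function(o)
      grep(paste0("^", o), names(coef(full$fit)), value = TRUE))))
    if (!length(rows) || all(rows %in% aliased)) {
      return(tibble::tibble(exposure = e, level = NA_character_,
                            or = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, p_wald = NA_real_,
                            flagged = TRUE))
    }
    rows <- setdiff(rows, aliased)
    est <- cf[rows, 1]; se <- cf[rows, 2]
    ci <- or_ci(est, se)
    lev <- sub(paste0("^", e), "", rows)
    lev[lev == ""] <- NA_character_
    tibble::tibble(exposure = e, level = lev, or = ci$or,
                   ci_low = ci$ci_low, ci_high = ci$ci_high,
                   p_wald = cf[rows, 4], flagged = full$flagged)
  })
  out <- dplyr::bind_rows(rows_all)
  attr(out, "fit_full") <- full$fit
  class(out) <- c("pd_assoc_result", class(out))
  out
}

#' Matched case-control sub-cohort
#'
#' For each incident case, samples without replacement exactly `ratio`
#' controls with identical sex and ethnicity and age within `age_tol` years.
#' Cases with too few eligible controls are dropped with a warning. Sampling
#' is deterministic under `seed`; each control is used at most once.
#'
#' @param cohort Cohort tibble.
#' @param ratio Controls per case (default 4).
#' @param age_tol Age matching tolerance in years (default 1).
#' @param seed Integer seed.
#' @return Tibble: the retained cases and their matched controls, with a
#'   `match_id` column linking each matched set.
#' @export
matched_design <- function(cohort, ratio = 4, age_tol = 1, seed = 1L) {
  cases <- cohort[cohort$pd_status == 1 & cohort$incident == 1, , drop = FALSE]
  controls <- cohort[cohort$pd_status == 0, , drop = FALSE]
  cases <- cases[order(cases$id), , drop = FALSE]
  withr::with_seed(child_seed(seed, 5L), {
    available <- rep(TRUE, nrow(controls))
    picked <- list()
    dropped <- 0L
    for (i in seq_len(nrow(cases))) {
      elig <- which(available &
                      controls$sex == cases$sex[i] &
                      controls$ethnicity == cases$ethnicity[i] &
                      abs(controls$age - cases$age[i]) <= age_tol)
      if (length(elig) < ratio) {
        dropped <- dropped + 1L
        next
      }
      sel <- if (length(elig) == ratio) elig else sample(elig, ratio)
      available[sel] <- FALSE
      case_row <- cases[i, , drop = FALSE]
      ctrl_rows <- controls[sel, , drop = FALSE]
      set <- dplyr::bind_rows(case_row, ctrl_rows)
      set$match_id <- cases$id[i]
      picked[[length(picked) + 1L]] <- set
    }
    if (dropped > 0) {
      warning(dropped, " case(s) dropped: fewer than ", ratio,
              " eligible controls", call. = FALSE)
    }
    if (!length(picked)) {
      out <- cohort[0, , drop = FALSE]
      out$match_id <- character()
      return(tibble::as_tibble(out))
    }
    tibble::as_tibble(dplyr::bind_rows(picked))
  })
}
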
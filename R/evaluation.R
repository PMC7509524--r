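#' Stratified train/test split
#'
#' Randomly assigns individuals to a training set (fraction
#' `train_fraction`) and a testing set, stratified by case status so both
#' splits carry their share of cases; deterministic under `seed`; splits
#' are disjoint and exhaustive.
#'
#' @param cohort Cohort tibble with an `id` column.
#' @param train_fraction Training fraction in (0, 1) (default 0.30).
#' @param outcome Stratification column (binary).
#' @param seed Integer seed.
#' @return List of class `pd_split`: `train_ids`, `test_ids`.
#' @export
split_cohort <- function(cohort, train_fraction = 0.30,
                         outcome = "pd_status", seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  withr::with_seed(child_seed(seed, 7L), {
    train <- character()
    for (lev in unique(cohort[[outcome]])) {
      ids <- cohort$id[cohort[[outcome]] == lev]
      n_train <- round(train_fraction * length(ids))
      train <- c(train, sample(ids, n_train))
    }
    test <- setdiff(cohort$id, train)
    n_cases_train <- sum(cohort[[outcome]][cohort$id %in% train] == 1)
    n_cases_test <- sum(cohort[[outcome]][cohort$id %in% test] == 1)
    if (min(n_cases_train, n_cases_test) < 10) {
      warning("fewer than 10 cases in one split", call. = FALSE)
    }
    structure(list(train_ids = sort(train), test_ids = sort(test)),
              class = "pd_split")
  })
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell `R2 = 1 - exp(2 * (ll_null - ll_full) / n)` rescaled by its
#' maximum `1 - exp(2 * ll_null / n)` so a perfect model scores 1.
#'
#' @param ll_null,ll_full Log-likelihoods of the nested null and full
#'   models; `ll_full >= ll_null` required.
#' @param n Number of observations.
#' @return Pseudo-R-squared in `[0, 1]`.
#' @examples
#' nagelkerke(100 * log(0.5), -50, 100) # ~0.427395
#' @export
nagelkerke <- function(ll_null, ll_full, n) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (ll_full < ll_null - 1e-8) {
    stop("ll_full < ll_null: models are not nested or a fit failed",
         call. = FALSE)
  }
  cox_snell <- 1 - exp(2 * (ll_null - ll_full) / n)
  max_r2 <- 1 - exp(2 * ll_null / n)
  if (max_r2 <= 0) return(0)
  min(1, cox_snell / max_r2)
}

#' Bootstrap a scalar metric with a normal-approximation CI
#'
#' Resamples rows of `data` with replacement, recomputes the metric per
#' replicate, and reports `estimate +/- 1.96 * SD(replicates)`. Failed
#' replicates are counted; results with more than `max_fail_frac` failures
#' are flagged.
#'
#' @param metric_fn Function taking a data frame and returning one number.
#' @param data Data frame of observations.
#' @param n_boot Replicates (default 1000).
#' @param seed Integer seed.
#' @param max_fail_frac Failure tolerance (default 0.1).
#' @return List: `estimate`, `se`, `ci_low`, `ci_high`, `n_boot`,
#'   `n_failed`, `flagged`.
#' @export
bootstrap_metric <- function(metric_fn, data, n_boot = 1000, seed = 1L,
                             max_fail_frac = 0.1) {
  est <- metric_fn(data)
  n <- nrow(data)
  reps <- rep(NA_real_, n_boot)
  withr::with_seed(child_seed(seed, 8L), {
    for (b in seq_len(n_boot)) {
      rows <- sample.int(n, n, replace = TRUE)
      reps[b] <- tryCatch(metric_fn(data[rows, , drop = FALSE]),
                          error = function(e) NA_real_)
    }
  })
  ok <- !is.na(reps)
  se <- if (sum(ok) > 1) sd(reps[ok]) else NA_real_
  list(estimate = est, se = se,
       ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
       n_boot = n_boot, n_failed = sum(!ok),
       flagged = sum(!ok) > max_fail_frac * n_boot)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with tie correction: the probability that
#' a random case scores above a random control, counting ties as one half.
#'
#' @param scores Numeric predictions.
#' @param labels Binary labels (0/1); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Calibration slope and intercept
#'
#' Logistic regression of the observed labels on the log-odds of the
#' predicted probabilities; slope 1 and intercept 0 indicate perfect
#' calibration.
#'
#' @param predicted Predicted probabilities in (0, 1).
#' @param labels Binary labels.
#' @return List: `slope`, `intercept`.
#' @export
calibration <- function(predicted, labels) {
  stopifnot(all(predicted > 0 & predicted < 1))
  lo <- qlogis(predicted)
  fit <- glm(labels ~ lo, family = binomial())
  list(slope = unname(coef(fit)["lo"]),
       intercept = unname(coef(fit)["(Intercept)"]))
}

#' Compare risk models on a test cohort
#'
#' Fits three nested logistic models on the test set: (a) the clinical
#' risk algorithm's log-odds plus the first four principal components,
#' (b) model (a) plus the polygenic score, and optionally (c) model (a)
#' plus the known-loci-excluded score. Reports Nagelkerke pseudo-R-squared,
#' AUC and calibration per model, and the incremental pseudo-R-squared and
#' likelihood-ratio test of (b) and (c) over (a).
#'
#' @param cohort Test cohort tibble.
#' @param predictpd_log_odds Column name of the clinical-algorithm log-odds.
#' @param prs Column name of the polygenic score.
#' @param prs_excluded Optional column name of the loci-excluded score.
#' @param outcome Binary outcome column.
#' @param pcs Principal-component columns.
#' @return Tibble of class `pd_model_comparison`: one row per model with
#'   `model`, `nagelkerke_r2`, `auc`, `calibration_slope`,
#'   `calibration_intercept`, `incremental_r2`, `lrt_p_vs_base`.
#' @export
compare_models <- function(cohort, predictpd_log_odds = "log_odds",
                           prs = "score_int", prs_excluded = NULL,
                           outcome = "pd_status",
                           pcs = c("pc1", "pc2", "pc3", "pc4")) {
  for (col in c(predictpd_log_odds, prs, prs_excluded)) {
    if (!col %in% names(cohort)) {
      stop("missing model component column: ", col, call. = FALSE)
    }
  }
  base_terms <- c(predictpd_log_odds, pcs)
  cols <- unique(c(outcome, base_terms, prs, prs_excluded))
  dat <- cohort[complete.cases(cohort[, cols, drop = FALSE]), , drop = FALSE]
  fit_one <- function(terms) {
    f <- as.formula(paste(outcome, "~", paste(terms, collapse = " + ")))
    glm(f, data = dat, family = binomial())
  }
  null_fit <- glm(as.formula(paste(outcome, "~ 1")), data = dat,
                  family = binomial())
  ll0 <- as.numeric(logLik(null_fit))
  n <- nrow(dat)
  metrics <- function(fit, base_fit = NULL) {
    ll <- as.numeric(logLik(fit))
    pred <- predict(fit, type = "response")
    cal <- calibration(pmin(pmax(pred, 1e-12), 1 - 1e-12), dat[[outcome]])
    row <- tibble::tibble(
      nagelkerke_r2 = nagelkerke(ll0, ll, n),
      auc = auc(predict(fit, type = "link"), dat[[outcome]]),
      calibration_slope = cal$slope,
      calibration_intercept = cal$intercept,
      incremental_r2 = NA_real_, lrt_p_vs_base = NA_real_
    )
    if (!is.null(base_fit)) {
      llb <- as.numeric(logLik(base_fit))
      row$incremental_r2 <- nagelkerke(llb, max(ll, llb), n)
      row$lrt_p_vs_base <- lrt(fit, base_fit)$p
    }
    row
  }
  base_fit <- fit_one(base_terms)
  prs_fit <- fit_one(c(base_terms, prs))
  out <- dplyr::bind_rows(
    dplyr::mutate(metrics(base_fit), model = "base", .before = 1),
    dplyr::mutate(metrics(prs_fit, base_fit), model = "base_plus_prs",
                  .before = 1)
  )
  if (!is.null(prs_excluded)) {
    ex_fit <- fit_one(c(base_terms, prs_excluded))
    out <- dplyr::bind_rows(
      out,
      dplyr::mutate(metrics(ex_fit, base_fit),
                    model = "base_plus_prs_excluded", .before = 1)
    )
  }
  class(out) <- c("pd_model_comparison", class(out))
  out
}
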
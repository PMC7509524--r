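#' PREDICT-PD baseline-odds constants
#'
#' Constants of the age-based baseline odds equation
#' `odds(age) = 1 / (1 + c0 + c1 * exp(-k * (age - age_ref)))`:
#' the odds increase monotonically with age towards the asymptote
#' `1 / (1 + c0)`.
#'
#' @param c0,c1 Positive constants of the published equation.
#' @param k Age rate constant per year.
#' @param age_ref Reference age in years.
#' @return A list of class `pd_predictpd_baseline`.
#' @export
predictpd_baseline <- function(c0 = 28.53049, c1 = 73.67057,
                               k = 0.165308, age_ref = 60) {
  stopifnot(c0 > 0, c1 > 0, k > 0)
  structure(list(c0 = c0, c1 = c1, k = k, age_ref = age_ref),
            class = "pd_predictpd_baseline")
}

#' PREDICT-PD trait multiplier table
#'
#' Published odds multipliers for risk and protective traits: female sex
#' divides the odds by 1.5; current smoking multiplies by 0.44, previous
#' smoking by 0.78, family history of PD by 4.45, more than one cup of
#' coffee per day by 0.67, more than one alcoholic drink per week by 0.9,
#' constipation by 2.34, anxiety or depression by 1.86 and erectile
#' dysfunction by 3.8 (males only).
#'
#' @param ... Named overrides for individual factors (e.g.
#'   `family_history_pd = 4.0`).
#' @return Named numeric vector of class `pd_multiplier_table`; the `female`
#'   entry is stored as the divisor 1.5 and applied as a division.
#' @export
multiplier_table <- function(...) {
  tab <- c(
    female = 1.5, # divisor
    smoking_current = 0.44,
    smoking_previous = 0.78,
    family_history_pd = 4.45,
    coffee_gt1cup = 0.67,
    alcohol_gt1wk = 0.9,
    constipation = 2.34,
    anxiety_or_depression = 1.86,
    erectile_dysfunction = 3.8
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(tab))
    if (length(bad)) stop("unknown multiplier(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    tab[names(over)] <- unlist(over)
  }
  if (any(tab <= 0)) stop("all multipliers must be positive", call. = FALSE)
  structure(tab, class = "pd_multiplier_table")
}

#' Age-based baseline odds of Parkinson's disease
#'
#' @param age Age in years (finite, positive); vectorised.
#' @param baseline A [predictpd_baseline()].
#' @return Baseline odds, strictly increasing in age and bounded above by
#'   `1 / (1 + c0)`.
#' @examples
#' baseline_odds(60) # ~0.0096899
#' @export
baseline_odds <- function(age, baseline = predictpd_baseline()) {
  if (!is.numeric(age) || any(!is.finite(age)) || any(age <= 0)) {
    stop("age must be finite and positive", call. = FALSE)
  }
  1 / (1 + baseline$c0 + baseline$c1 * exp(-baseline$k * (age - baseline$age_ref)))
}

#' Apply PREDICT-PD trait multipliers to baseline odds
#'
#' Multiplies the age-based baseline odds by each applicable trait factor
#' (dividing by 1.5 for females). Factors are independent and commutative.
#' The erectile dysfunction multiplier is skipped (not imputed to 1) for
#' females; missing trait values count as absent.
#'
#' @param odds Positive baseline odds (vectorised; recycled against the
#'   profile columns).
#' @param profile Data frame or list with logical/flag columns `female`,
#'   `family_history_pd`, `coffee_gt1cup`, `alcohol_gt1wk`, `constipation`,
#'   `anxiety_or_depression`, `erectile_dysfunction` and a `smoking` column
#'   in `{"never", "previous", "current"}`. Absent columns count as absent
#'   traits.
#' @param table A [multiplier_table()].
#' @return Adjusted odds.
#' @examples
#' b <- baseline_odds(60)
#' apply_profile(b, list(family_history_pd = TRUE)) / b # 4.45
#' @export
apply_profile <- function(odds, profile, table = multiplier_table()) {
  if (any(odds <= 0)) stop("odds must be positive", call. = FALSE)
  profile <- as.list(profile)
  get_flag <- function(name) {
    v <- profile[[name]]
    if (is.null(v)) return(FALSE)
    v <- as.logical(v)
    v[is.na(v)] <- FALSE
    v
  }
  smoking <- profile$smoking %||% "never"
  smoking[is.na(smoking)] <- "never"
  if (!all(smoking %in% c("never", "previous", "current"))) {
    stop("smoking must be one of never/previous/current", call. = FALSE)
  }
  female <- get_flag("female")
  out <- odds
  out <- out / ifelse(female, table[["female"]], 1)
  out <- out * ifelse(smoking == "current", table[["smoking_current"]], 1)
  out <- out * ifelse(smoking == "previous", table[["smoking_previous"]], 1)
  for (tr in c("family_history_pd", "coffee_gt1cup", "alcohol_gt1wk",
               "constipation", "anxiety_or_depression")) {
    out <- out * ifelse(get_flag(tr), table[[tr]], 1)
  }
  ed <- get_flag("erectile_dysfunction") & !female # sex-specific trait
  out <- out * ifelse(ed, table[["erectile_dysfunction"]], 1)
  out
}

#' Batch PREDICT-PD risk for a cohort table
#'
#' Computes the age-based baseline odds, applies trait multipliers from the
#' cohort's columns, and returns odds, probability and log-odds per
#' individual. Column mapping: `sex == "female"` sets the female divisor;
#' `anxiety_or_depression` may be supplied directly or is taken as the
#' logical OR of `anxiety` and `depression` columns when present.
#'
#' @param cohort Tibble with at least `id` and `age`; recognised optional
#'   columns: `sex`, `smoking`, `family_history_pd` (or `family_history`),
#'   `coffee_gt1cup`, `alcohol_gt1wk`, `constipation`, `anxiety`,
#'   `depression`, `anxiety_or_depression`, `erectile_dysfunction`.
#' @param baseline A [predictpd_baseline()].
#' @param table A [multiplier_table()].
#' @return Tibble: `id`, `odds`, `prob`, `log_odds`.
#' @export
predictpd_risk <- function(cohort, baseline = predictpd_baseline(),
                           table = multiplier_table()) {
  stopifnot(all(c("id", "age") %in% names(cohort)))
  n <- nrow(cohort)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(cohort)) return(cohort[[nm]])
    rep(FALSE, n)
  }
  anx <- if ("anxiety_or_depression" %in% names(cohort)) {
    cohort$anxiety_or_depression
  } else {
    as.logical(pick("anxiety")) | as.logical(pick("depression"))
  }
  profile <- list(
    female = if ("sex" %in% names(cohort)) cohort$sex == "female" else
      rep(FALSE, n),
    smoking = if ("smoking" %in% names(cohort)) cohort$smoking else
      rep("never", n),
    family_history_pd = pick("family_history_pd", "family_history"),
    coffee_gt1cup = pick("coffee_gt1cup"),
    alcohol_gt1wk = pick("alcohol_gt1wk"),
    constipation = pick("constipation"),
    anxiety_or_depression = anx,
    erectile_dysfunction = pick("erectile_dysfunction")
  )
  odds <- apply_profile(baseline_odds(cohort$age, baseline), profile, table)
  tibble::tibble(
    id = cohort$id,
    odds = odds,
    prob = odds_to_probability(odds),
    log_odds = log_odds(odds)
  )
}
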
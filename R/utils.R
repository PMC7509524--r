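#' Rank-based inverse normal transformation
#'
#' Maps a numeric vector to standard-normal quantiles using the Blom offset:
#' `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for ties. The result
#' is invariant to any monotone transformation of the input and has mean
#' approximately 0 and standard deviation approximately 1.
#'
#' @param x Numeric vector with at least two distinct non-missing values.
#' @param na.rm Keep `NA`s as `NA` in the output (ranks are computed on the
#'   non-missing values). Defaults to `TRUE`.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' inverse_normal_transform(c(1, 2, 3))
#' @export
inverse_normal_transform <- function(x, na.rm = TRUE) {
  stopifnot(is.numeric(x))
  ok <- !is.na(x)
  vals <- x[ok]
  if (length(unique(vals)) < 2) {
    stop("inverse_normal_transform() needs at least 2 distinct values", call. = FALSE)
  }
  n <- length(vals)
  r <- rank(vals, ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  if (!na.rm && anyNA(out)) stop("missing values present", call. = FALSE)
  out
}

#' Odds, probability and log-odds conversions
#'
#' Mutually inverse maps between the odds, probability and log-odds scales,
#' used when combining multiplicative risk algorithms with logistic models.
#'
#' @param odds Non-negative odds.
#' @param p Probability in \[0, 1).
#' @return Numeric vector.
#' @examples
#' odds_to_probability(1) # 0.5
#' probability_to_odds(odds_to_probability(0.25))
#' @export
odds_to_probability <- function(odds) {
  check_odds(odds)
  odds / (1 + odds)
}

#' @rdname odds_to_probability
#' @export
probability_to_odds <- function(p) {
  stopifnot(is.numeric(p), all(is.finite(p)), all(p >= 0), all(p < 1))
  p / (1 - p)
}

#' @rdname odds_to_probability
#' @export
log_odds <- function(odds) {
  check_odds(odds)
  log(odds)
}

check_odds <- function(odds) {
  if (!is.numeric(odds) || any(!is.finite(odds)) || any(odds < 0)) {
    stop("odds must be finite and non-negative", call. = FALSE)
  }
  invisible(odds)
}

# Deterministic child seeds: one global seed governs per-component streams.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12345L) %% 2147483629L
}

# Fast logistic refits for bootstrap loops: model matrix built once, rows
# resampled by index. Same IRLS as glm(), minus formula overhead.
fit_logit_mm <- function(X, y, w = NULL) {
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(), weights = w,
            control = list(epsilon = 1e-8, maxit = 100))
  )
  fit
}

logLik_glmfit <- function(fit) {
  mu <- fit$fitted.values
  y <- fit$y
  sum(y * log(mu) + (1 - y) * log(1 - mu))
}

# Wald CI helper for glm coefficient rows, on the OR scale
or_ci <- function(est, se, level = 0.95) {
  est <- unname(est)
  se <- unname(se)
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    or = exp(est),
    ci_low = exp(est - z * se),
    ci_high = exp(est + z * se)
  )
}
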
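#' Clumping-and-thresholding grid
#'
#' The candidate grid for polygenic score construction: p-value inclusion
#' thresholds, LD r-squared clumping thresholds, and the clumping window.
#'
#' @param p_thresholds P-value thresholds in (0, 1]; a threshold of 1 keeps
#'   every variant.
#' @param r2_thresholds LD r-squared thresholds in (0, 1].
#' @param clump_window_kb Clumping distance in kilobases (> 0).
#' @return A list of class `pd_ct_grid`.
#' @export
ct_grid <- function(p_thresholds = c(5e-05, 5e-04, 5e-03, 0.05, 0.1, 0.2,
                                     0.4, 0.6, 0.8, 1),
                    r2_thresholds = c(0.1, 0.2, 0.4, 0.6, 0.8),
                    clump_window_kb = 250) {
  stopifnot(all(p_thresholds > 0), all(p_thresholds <= 1),
            all(r2_thresholds > 0), all(r2_thresholds <= 1),
            clump_window_kb > 0)
  structure(list(p_thresholds = p_thresholds, r2_thresholds = r2_thresholds,
                 clump_window_kb = clump_window_kb),
            class = "pd_ct_grid")
}

#' Greedy LD clumping
#'
#' Sorts variants by ascending p-value (ties broken by position, then rsid),
#' repeatedly takes the best unclaimed variant as the index, and claims all
#' unclaimed variants on the same chromosome within `window_kb` whose dosage
#' correlation r-squared with the index — squared Pearson correlation on the
#' reference panel, pairwise-complete — is at least `r2_threshold`. The index
#' variants form the retained set.
#'
#' @param stats Summary-statistics tibble (`rsid`, `chrom`, `pos`, `p`).
#' @param reference A `pd_genotypes` reference panel containing the
#'   candidate variants; variants absent from the panel are dropped with a
#'   warning.
#' @param r2_threshold LD r-squared at or above which a variant is claimed.
#' @param window_kb Clumping distance in kilobases.
#' @return Character vector of retained (index) variant ids.
#' @export
clump <- function(stats, reference, r2_threshold = 0.4, window_kb = 250) {
  stopifnot(inherits(reference, "pd_genotypes"))
  missing_ref <- setdiff(stats$rsid, reference$variants$rsid)
  if (length(missing_ref)) {
    warning(length(missing_ref), " variant(s) absent from reference panel; excluded",
            call. = FALSE)
    stats <- stats[!stats$rsid %in% missing_ref, , drop = FALSE]
  }
  if (nrow(stats) == 0) return(character())
  ord <- order(stats$p, stats$pos, stats$rsid)
  stats <- stats[ord, , drop = FALSE]
  D <- reference$dosages
  col <- match(stats$rsid, colnames(D))
  window <- window_kb * 1000
  n <- nrow(stats)
  state <- rep("free", n) # free / index / claimed
  for (i in seq_len(n)) {
    if (state[i] != "free") next
    state[i] <- "index"
    cand <- which(state == "free" &
                    stats$chrom == stats$chrom[i] &
                    abs(stats$pos - stats$pos[i]) <= window)
    if (!length(cand)) next
    xi <- D[, col[i]]
    r <- suppressWarnings(
      cor(xi, D[, col[cand], drop = FALSE], use = "pairwise.complete.obs")
    )
    r2 <- drop(r)^2
    r2[is.na(r2)] <- 0
    state[cand[r2 >= r2_threshold]] <- "claimed"
  }
  stats$rsid[state == "index"]
}

new_prs_model <- function(variants, p_threshold, r2_threshold) {
  structure(
    list(variants = variants, # tibble: rsid, chrom, pos, a1, a2, beta, mean, sd
         p_threshold = p_threshold, r2_threshold = r2_threshold,
         n_snps = nrow(variants)),
    class = "pd_prs_model"
  )
}

#' @export
print.pd_prs_model <- function(x, ...) {
  cat("<pd_prs_model> ", x$n_snps, " SNPs (p < ", format(x$p_threshold),
      ", clump r2 ", format(x$r2_threshold), ")\n", sep = "")
  invisible(x)
}

# Per-locus score standardisation constants (mean and SD of dosage * beta)
# estimated on the given panel and frozen into the model.
fit_standardisation <- function(model, genotypes) {
  v <- model$variants
  d <- aligned_dosages(genotypes, v)
  s <- sweep(d, 2, v$beta, `*`)
  v$mean <- unname(colMeans(s, na.rm = TRUE))
  sds <- unname(apply(s, 2, sd, na.rm = TRUE))
  sds[!is.finite(sds) | sds == 0] <- NA_real_
  v$sd <- sds
  model$variants <- v
  model
}

# Dosage matrix for the model's variants, oriented to the model's effect
# allele: if the genotype file counts the other allele, dosage is flipped to
# 2 - dosage. Variants absent (or allele-incompatible) come back as all-NA
# columns.
aligned_dosages <- function(genotypes, model_variants) {
  D <- genotypes$dosages
  gv <- genotypes$variants
  idx <- match(model_variants$rsid, gv$rsid)
  out <- matrix(NA_real_, nrow(D), nrow(model_variants))
  for (j in seq_along(idx)) {
    gi <- idx[j]
    if (is.na(gi)) next
    d <- as.numeric(D[, gi])
    if (gv$a1[gi] == model_variants$a1[j]) {
      out[, j] <- d
    } else if (gv$a2[gi] == model_variants$a1[j]) {
      out[, j] <- 2 - d
    } # otherwise allele mismatch: leave NA
  }
  rownames(out) <- genotypes$sample_ids
  colnames(out) <- model_variants$rsid
  out
}

#' Build candidate polygenic score models over a C+T grid
#'
#' One candidate per (p-threshold, r-squared threshold) pair: variants with
#' `p < p_threshold` (a threshold of 1 keeps all) are clumped on the
#' reference panel, summary-statistic betas become the weights, and per-locus
#' standardisation constants are estimated on the training panel and frozen.
#' Grid cells with no surviving variant are flagged empty and skipped during
#' selection.
#'
#' @param stats Summary-statistics tibble.
#' @param reference Reference `pd_genotypes` for LD.
#' @param grid A [ct_grid()].
#' @param train_genotypes Training-panel `pd_genotypes` used for
#'   standardisation (defaults to the reference panel).
#' @return List of `pd_prs_model` objects (empty cells carry `n_snps = 0`).
#' @export
build_candidates <- function(stats, reference, grid = ct_grid(),
                             train_genotypes = reference) {
  out <- list()
  for (r2 in grid$r2_thresholds) {
    for (pt in grid$p_thresholds) {
      sub <- if (pt >= 1) stats else stats[stats$p < pt, , drop = FALSE]
      if (nrow(sub) == 0) {
        out[[length(out) + 1L]] <- new_prs_model(
          tibble::tibble(rsid = character(), chrom = character(),
                         pos = integer(), a1 = character(), a2 = character(),
                         beta = numeric(), mean = numeric(), sd = numeric()),
          pt, r2)
        next
      }
      kept <- clump(sub, reference, r2_threshold = r2,
                    window_kb = grid$clump_window_kb)
      v <- sub[match(kept, sub$rsid), c("rsid", "chrom", "pos", "a1", "a2", "beta")]
      model <- new_prs_model(tibble::as_tibble(v), pt, r2)
      out[[length(out) + 1L]] <- fit_standardisation(model, train_genotypes)
    }
  }
  out
}

#' Score individuals with a polygenic risk score model
#'
#' The per-locus score is effect-allele dosage times beta, standardised by
#' the model's frozen per-locus mean and SD; missing dosages (and model
#' variants absent from the genotypes) contribute the per-locus mean, i.e.
#' exactly 0 after standardisation. The total is the sum over loci. Dosages
#' counted on the opposite allele are flipped to `2 - dosage` before scoring.
#' The inverse-normal-transformed score and decile assignment (1 = lowest)
#' are computed on the scored set.
#'
#' @param genotypes A `pd_genotypes`.
#' @param model A fitted `pd_prs_model` (standardisation constants present).
#' @param max_absent_frac Error if more than this fraction of model variants
#'   is absent from the genotypes (default 0.5).
#' @return Tibble: `id`, `score`, `score_int`, `decile`.
#' @export
prs_score <- function(genotypes, model, max_absent_frac = 0.5) {
  stopifnot(inherits(model, "pd_prs_model"))
  v <- model$variants
  if (model$n_snps == 0) stop("empty PRS model", call. = FALSE)
  if (is.null(v$mean) || is.null(v$sd)) {
    stop("model standardisation constants not fitted", call. = FALSE)
  }
  absent <- !(v$rsid %in% genotypes$variants$rsid)
  if (mean(absent) > max_absent_frac) {
    stop(sum(absent), " of ", length(absent),
         " model variants absent from genotypes", call. = FALSE)
  }
  d <- aligned_dosages(genotypes, v)
  s <- sweep(d, 2, v$beta, `*`)
  z <- sweep(sweep(s, 2, v$mean, `-`), 2, v$sd, `/`)
  z[is.na(z)] <- 0 # missing/absent/zero-SD loci sit at the per-locus mean
  total <- unname(rowSums(z))
  score_int <- if (length(unique(total)) >= 2) {
    inverse_normal_transform(total)
  } else rep(NA_real_, length(total))
  tibble::tibble(
    id = genotypes$sample_ids,
    score = total,
    score_int = score_int,
    decile = dplyr::ntile(total, 10)
  )
}

#' Select the best candidate score by Nagelkerke pseudo-R-squared
#'
#' For each candidate, individuals are scored and the logistic model
#' `outcome ~ covariates + PRS` is compared with the same model without the
#' PRS via Nagelkerke's pseudo-R-squared on the training individuals. An
#' optional bootstrap (normal-approximation CI) is attached. The candidate
#' with the highest pseudo-R-squared wins; ties go to the model with fewer
#' SNPs. Non-converged candidates are flagged and excluded.
#'
#' @param candidates List of fitted `pd_prs_model`s.
#' @param genotypes Training `pd_genotypes`.
#' @param cohort Training cohort tibble (joined to scores by `id`).
#' @param outcome Outcome column (default `pd_status`).
#' @param covariates Covariate columns for both nested models.
#' @param n_boot Bootstrap replicates for the R-squared CI (0 disables).
#' @param seed Seed for the bootstrap.
#' @return List of class `pd_prs_selection`: `best` (a `pd_prs_model`),
#'   `table` (one row per candidate: grid cell, n_snps, r2_nagelkerke,
#'   optional CI, convergence flag).
#' @export
select_best <- function(candidates, genotypes, cohort,
                        outcome = "pd_status",
                        covariates = c("age", "sex", "townsend",
                                       "pc1", "pc2", "pc3", "pc4"),
                        n_boot = 0, seed = 1L) {
  rows <- vector("list", length(candidates))
  for (k in seq_along(candidates)) {
    m <- candidates[[k]]
    row <- tibble::tibble(p_threshold = m$p_threshold,
                          r2_threshold = m$r2_threshold,
                          n_snps = m$n_snps,
                          r2_nagelkerke = NA_real_,
                          r2_ci_low = NA_real_, r2_ci_high = NA_real_,
                          converged = FALSE)
    if (m$n_snps > 0) {
      sc <- prs_score(genotypes, m)
      dat <- dplyr::inner_join(cohort, sc, by = "id")
      fit <- tryCatch(
        nagelkerke_vs_null(dat, outcome, covariates, "score"),
        error = function(e) NULL
      )
      if (!is.null(fit) && is.finite(fit$r2)) {
        row$r2_nagelkerke <- fit$r2
        row$converged <- TRUE
        if (n_boot > 0) {
          ci <- bootstrap_metric(
            function(d) nagelkerke_vs_null(d, outcome, covariates, "score")$r2,
            dat, n_boot = n_boot, seed = seed
          )
          row$r2_ci_low <- ci$ci_low
          row$r2_ci_high <- ci$ci_high
        }
      }
    }
    rows[[k]] <- row
  }
  tab <- dplyr::bind_rows(rows)
  ok <- which(tab$converged)
  if (!length(ok)) stop("no candidate model converged", call. = FALSE)
  ord <- ok[order(-tab$r2_nagelkerke[ok], tab$n_snps[ok])]
  best_idx <- ord[1]
  structure(list(best = candidates[[best_idx]], best_index = best_idx,
                 table = tab),
            class = "pd_prs_selection")
}

# Nagelkerke R2 of outcome ~ covariates + extra vs outcome ~ covariates,
# on complete cases of the full model.
nagelkerke_vs_null <- function(data, outcome, covariates, extra) {
  cols <- unique(c(outcome, covariates, extra))
  dat <- data[complete.cases(data[, cols, drop = FALSE]), cols, drop = FALSE]
  f_full <- as.formula(paste(outcome, "~",
                             paste(c(covariates, extra), collapse = " + ")))
  f_null <- if (length(covariates)) {
    as.formula(paste(outcome, "~", paste(covariates, collapse = " + ")))
  } else as.formula(paste(outcome, "~ 1"))
  full <- glm(f_full, data = dat, family = binomial())
  null <- glm(f_null, data = dat, family = binomial())
  list(
    r2 = nagelkerke(as.numeric(logLik(null)), as.numeric(logLik(full)),
                    nrow(dat)),
    ll_full = as.numeric(logLik(full)), ll_null = as.numeric(logLik(null)),
    df = length(coef(full)) - length(coef(null)),
    full = full, null = null, n = nrow(dat)
  )
}

#' Per-decile odds ratios for a polygenic score
#'
#' Assigns deciles on the supplied score distribution (1 = lowest) and fits
#' a logistic model of the outcome on the decile indicator (reference decile
#' 1) plus covariates; returns OR and Wald 95% CI per decile. Deciles with an
#' empty case or control cell are flagged and their CI is reported as
#' unbounded.
#'
#' @param scores Score tibble from [prs_score()] (`id`, `score`).
#' @param cohort Cohort tibble.
#' @param outcome Outcome column.
#' @param covariates Covariate columns (may be empty for a crude model).
#' @return Tibble of class `pd_decile_table`: `decile`, `n_cases`,
#'   `n_controls`, `or`, `ci_low`, `ci_high`, `flagged`.
#' @export
decile_analysis <- function(scores, cohort, outcome = "pd_status",
                            covariates = c("age", "sex", "townsend",
                                           "pc1", "pc2", "pc3", "pc4")) {
  dat <- cohort
  dat$score <- scores$score[match(dat$id, scores$id)]
  dat <- dat[!is.na(dat$score), , drop = FALSE]
  dat$decile <- dplyr::ntile(dat$score, 10)
  counts <- dat |>
    dplyr::group_by(.data$decile) |>
    dplyr::summarise(n_cases = sum(.data[[outcome]] == 1),
                     n_controls = sum(.data[[outcome]] == 0),
                     .groups = "drop")
  dat$decile_f <- factor(dat$decile, levels = 1:10)
  rhs <- c("decile_f", covariates)
  f <- as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  fit <- glm(f, data = dat, family = binomial())
  cf <- summary(fit)$coefficients
  dec_rows <- paste0("decile_f", 2:10)
  est <- cf[match(dec_rows, rownames(cf)), 1]
  se <- cf[match(dec_rows, rownames(cf)), 2]
  ci <- or_ci(est, se)
  out <- tibble::tibble(
    decile = 1:10,
    or = c(1, ci$or),
    ci_low = c(1, ci$ci_low),
    ci_high = c(1, ci$ci_high)
  )
  out <- dplyr::left_join(counts, out, by = "decile")
  out$flagged <- out$n_cases == 0 | out$n_controls == 0
  out$ci_low[out$flagged] <- 0
  out$ci_high[out$flagged] <- Inf
  class(out) <- c("pd_decile_table", class(out))
  out
}

#' Age-at-diagnosis model for cases
#'
#' Linear model of age at diagnosis on the inverse-normal-transformed score,
#' adjusting for age, sex and the first four principal components, fitted on
#' cases only. A negative slope means higher polygenic load is associated
#' with earlier diagnosis.
#'
#' @param scores Score tibble (`id`, `score_int`).
#' @param cohort Cohort tibble; rows with `pd_status == 1` and a non-missing
#'   `age_at_diagnosis` are used.
#' @param covariates Adjustment covariates.
#' @param min_cases Minimum number of usable cases (default 30).
#' @return List of class `pd_onset_fit`: `slope` (years per SD), `se`, `p`,
#'   `ci_low`, `ci_high`, `n`, and the underlying `lm` fit.
#' @export
onset_model <- function(scores, cohort,
                        covariates = c("age", "sex", "pc1", "pc2", "pc3", "pc4"),
                        min_cases = 30) {
  dat <- cohort
  dat$score_int <- scores$score_int[match(dat$id, scores$id)]
  dat <- dat[!is.na(dat$score_int) & dat$pd_status == 1 &
               !is.na(dat$age_at_diagnosis), , drop = FALSE]
  if (nrow(dat) < min_cases) {
    stop("insufficient cases for the onset model (", nrow(dat), " < ",
         min_cases, ")", call. = FALSE)
  }
  f <- as.formula(paste("age_at_diagnosis ~ score_int +",
                        paste(covariates, collapse = " + ")))
  fit <- lm(f, data = dat)
  cf <- summary(fit)$coefficients["score_int", ]
  structure(
    list(slope = unname(cf[1]), se = unname(cf[2]), p = unname(cf[4]),
         ci_low = unname(cf[1] - 1.96 * cf[2]),
         ci_high = unname(cf[1] + 1.96 * cf[2]),
         n = nrow(dat), fit = fit),
    class = "pd_onset_fit"
  )
}

#' Remove variants near known risk loci from a score model
#'
#' Drops model variants within 1 Mb (inclusive) either side of any supplied
#' lead SNP on the same chromosome and re-fits the standardisation constants
#' on the supplied panel. Used to ask whether a score retains signal outside
#' established risk loci.
#'
#' @param model A `pd_prs_model`.
#' @param lead_snps Tibble with `chrom` and `pos` of lead SNPs (same build
#'   as the model variants). Zero rows leaves the model unchanged.
#' @param genotypes Panel used to re-fit standardisation (required when any
#'   variant is removed).
#' @param window_bp Exclusion half-window in base pairs (default 1e6,
#'   inclusive at the boundary).
#' @return A `pd_prs_model`.
#' @export
exclude_known_loci <- function(model, lead_snps, genotypes = NULL,
                               window_bp = 1e6) {
  stopifnot(inherits(model, "pd_prs_model"))
  lead_snps <- tibble::as_tibble(lead_snps)
  if (nrow(lead_snps) == 0 || model$n_snps == 0) return(model)
  v <- model$variants
  drop <- rep(FALSE, nrow(v))
  for (k in seq_len(nrow(lead_snps))) {
    drop <- drop | (v$chrom == as.character(lead_snps$chrom[k]) &
                      abs(v$pos - lead_snps$pos[k]) <= window_bp)
  }
  if (!any(drop)) return(model)
  out <- new_prs_model(v[!drop, , drop = FALSE], model$p_threshold,
                       model$r2_threshold)
  if (out$n_snps > 0) {
    if (is.null(genotypes)) {
      stop("genotypes needed to re-fit standardisation after exclusion",
           call. = FALSE)
    }
    out <- fit_standardisation(out, genotypes)
  }
  out
}
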
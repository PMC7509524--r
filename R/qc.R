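#' Quality-control thresholds
#'
#' Variant- and sample-level filter thresholds with field-standard defaults:
#' minor allele frequency >= 0.01 (strict `< 0.01` exclusion), per-variant
#' genotype missingness <= 10% (strict `> 0.10` exclusion), Hardy-Weinberg
#' p >= 1e-6, imputation quality >= 0.3, per-sample missingness <= 10%, and a
#' kinship cutoff of 0.0442 (third-degree relatives).
#'
#' @param maf_min,geno_missing_max,hwe_p_min,info_min,sample_missing_max,kinship_cutoff
#'   Numeric thresholds, all in `[0, 1]`.
#' @return A list of class `pd_qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01,
                          geno_missing_max = 0.10,
                          hwe_p_min = 1e-06,
                          info_min = 0.3,
                          sample_missing_max = 0.10,
                          kinship_cutoff = 0.0442) {
  vals <- c(maf_min, geno_missing_max, hwe_p_min, info_min,
            sample_missing_max, kinship_cutoff)
  if (any(vals < 0 | vals > 1)) stop("thresholds must be in [0, 1]", call. = FALSE)
  structure(
    list(maf_min = maf_min, geno_missing_max = geno_missing_max,
         hwe_p_min = hwe_p_min, info_min = info_min,
         sample_missing_max = sample_missing_max,
         kinship_cutoff = kinship_cutoff),
    class = "pd_qc_thresholds"
  )
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on observed genotype counts: the p-value sums the
#' probabilities of all heterozygote counts (for the observed allele counts)
#' no more likely than the observed one.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (hom ref, het, hom alt).
#' @return P-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_b <- 2 * n_bb + n_ab # minor-ish allele count; symmetric either way
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, n_b)
  if (n == 0 || rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_com <- (2 * n - rare - h) / 2
    lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(h + 1) - lgamma(hom_com + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(min(n_ab, rare), hets)
  min(1, sum(p[p <= p[obs] + 1e-12]))
}

#' Variant-level quality control
#'
#' Applies the variant filters in a fixed order and itemises removals:
#' (1) variants absent from the summary statistics, (2) duplicate rsIDs
#' (later occurrences removed, the first kept), (3) duplicate positions
#' (likewise), (4) palindromic variants (A/T or C/G),
#' (5) variants without an rsID, then (6) minor allele frequency `< maf_min`,
#' (7) per-variant missingness `> geno_missing_max`, (8) Hardy-Weinberg
#' `p < hwe_p_min` (from metadata when supplied, otherwise the exact test on
#' the analysis genotypes), and (9) imputation quality `< info_min`.
#' Boundary values are retained: the exclusions are strict inequalities.
#'
#' @param genotypes A `pd_genotypes`.
#' @param stats Summary-statistics tibble (needs an `rsid` column), or `NULL`
#'   to skip the overlap filter.
#' @param thresholds A [qc_thresholds()].
#' @return List with `genotypes` (filtered) and `report` (a tibble of class
#'   `pd_qc_report`: one row per filtering step with removal counts), plus
#'   `retained` (variant ids).
#' @export
filter_variants <- function(genotypes, stats = NULL,
                            thresholds = qc_thresholds()) {
  stopifnot(inherits(genotypes, "pd_genotypes"))
  v <- genotypes$variants
  D <- genotypes$dosages
  n_in <- nrow(v)
  keep <- rep(TRUE, n_in)
  steps <- list()
  note <- function(name, drop) {
    steps[[length(steps) + 1L]] <<- tibble::tibble(step = name,
                                                   removed = sum(drop & keep))
    keep <<- keep & !drop
  }
  if (!is.null(stats)) {
    in_stats <- v$rsid %in% stats$rsid
    if (!any(in_stats)) stop("no overlapping variants between genotypes and summary statistics",
                             call. = FALSE)
    note("absent_from_sumstats", !in_stats)
  } else {
    note("absent_from_sumstats", rep(FALSE, n_in))
  }
  note("duplicate_rsid", duplicated(v$rsid))
  poskey <- paste(v$chrom, v$pos)
  note("duplicate_position", duplicated(poskey))
  note("palindromic", is_palindromic(v$a1, v$a2))
  note("missing_rsid", is.na(v$rsid) | v$rsid == "" | v$rsid == ".")
  maf <- v$maf
  if (is.null(maf) || anyNA(maf)) {
    af <- colMeans(D, na.rm = TRUE) / 2
    emp <- pmin(af, 1 - af)
    maf[is.na(maf)] <- emp[is.na(maf)]
  }
  note("maf", maf < thresholds$maf_min)
  miss <- colMeans(is.na(D))
  note("missingness", miss > thresholds$geno_missing_max)
  hwe <- v$hwe_p
  if (is.null(hwe)) hwe <- rep(NA_real_, n_in)
  need <- which(is.na(hwe) & keep)
  for (j in need) {
    d <- D[, j]
    hwe[j] <- hwe_exact_test(sum(d == 0, na.rm = TRUE),
                             sum(d == 1, na.rm = TRUE),
                             sum(d == 2, na.rm = TRUE))
  }
  note("hwe", !is.na(hwe) & hwe < thresholds$hwe_p_min)
  info <- v$info
  if (is.null(info)) info <- rep(NA_real_, n_in)
  note("info", !is.na(info) & info < thresholds$info_min)
  report <- dplyr::bind_rows(steps)
  report <- dplyr::mutate(report, retained_after = n_in - cumsum(.data$removed))
  class(report) <- c("pd_qc_report", class(report))
  attr(report, "axis") <- "variants"
  attr(report, "n_input") <- n_in
  out <- new_pd_genotypes(D[, keep, drop = FALSE], v[keep, , drop = FALSE],
                          genotypes$sample_ids, genotypes$effects)
  if (!is.null(out$effects)) {
    out$effects <- out$effects[out$effects$rsid %in% out$variants$rsid, ,
                               drop = FALSE]
  }
  list(genotypes = out, report = report, retained = v$rsid[keep])
}

#' Sample-level quality control
#'
#' Removes samples with genotype missingness strictly above
#' `sample_missing_max`, then samples whose ethnicity label differs from
#' `ancestry_label`. Ancestry restriction is a label filter here; principal
#' components are carried as covariates downstream.
#'
#' @param genotypes A `pd_genotypes`.
#' @param cohort Cohort tibble with `id` and `ethnicity` columns, or `NULL`
#'   to skip the ancestry filter.
#' @param thresholds A [qc_thresholds()].
#' @param ancestry_label Ethnicity label retained (default "white_british").
#' @return List with `sample_ids` (retained), `genotypes` (subset) and
#'   `report`.
#' @export
filter_samples <- function(genotypes, cohort = NULL,
                           thresholds = qc_thresholds(),
                           ancestry_label = "white_british") {
  stopifnot(inherits(genotypes, "pd_genotypes"))
  ids <- genotypes$sample_ids
  n_in <- length(ids)
  keep <- rep(TRUE, n_in)
  steps <- list()
  note <- function(name, drop) {
    steps[[length(steps) + 1L]] <<- tibble::tibble(step = name,
                                                   removed = sum(drop & keep))
    keep <<- keep & !drop
  }
  miss <- rowMeans(is.na(genotypes$dosages))
  note("sample_missingness", miss > thresholds$sample_missing_max)
  if (!is.null(cohort)) {
    eth <- cohort$ethnicity[match(ids, cohort$id)]
    note("ancestry_label", is.na(eth) | eth != ancestry_label)
  } else {
    note("ancestry_label", rep(FALSE, n_in))
  }
  report <- dplyr::bind_rows(steps)
  report <- dplyr::mutate(report, retained_after = n_in - cumsum(.data$removed))
  class(report) <- c("pd_qc_report", class(report))
  attr(report, "axis") <- "samples"
  attr(report, "n_input") <- n_in
  out <- new_pd_genotypes(genotypes$dosages[keep, , drop = FALSE],
                          genotypes$variants, ids[keep], genotypes$effects)
  list(sample_ids = ids[keep], genotypes = out, report = report)
}

#' Prune related samples
#'
#' Builds the relatedness graph over pairs with kinship `>= cutoff` and
#' greedily removes the highest-degree sample (ties broken by lexicographic
#' id, so the result is deterministic) until no edge remains. In
#' multi-relative clusters this retains more individuals than dropping one
#' sample per pair.
#'
#' @param sample_ids Character vector of candidate samples.
#' @param pairs Kinship tibble (`id1`, `id2`, `kinship`).
#' @param cutoff Kinship threshold (default 0.0442, third-degree relatives).
#' @return Character vector of retained sample ids (original order).
#' @export
prune_related <- function(sample_ids, pairs, cutoff = 0.0442) {
  if (nrow(pairs) == 0) return(sample_ids)
  stopifnot(all(c("id1", "id2", "kinship") %in% names(pairs)))
  unknown <- setdiff(c(pairs$id1, pairs$id2), sample_ids)
  if (length(unknown)) {
    stop("kinship pairs reference unknown sample id(s): ",
         paste(head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  edges <- pairs[pairs$kinship >= cutoff & pairs$id1 != pairs$id2, c("id1", "id2")]
  removed <- character()
  while (nrow(edges) > 0) {
    deg <- table(c(edges$id1, edges$id2))
    worst <- names(deg)[deg == max(deg)]
    victim <- sort(worst)[1]
    removed <- c(removed, victim)
    edges <- edges[edges$id1 != victim & edges$id2 != victim, , drop = FALSE]
  }
  setdiff(sample_ids, removed)
}
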
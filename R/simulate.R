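#' Simulation configuration for a synthetic incident-disease cohort
#'
#' Bundles and validates every generative parameter of the synthetic cohort:
#' genotypes in LD blocks, an external GWAS layer, exposures, a logistic
#' incident-disease model with optional score-by-exposure interactions,
#' relatedness and ancestry principal components. Identical configuration and
#' seed give byte-identical output.
#'
#' @param n_individuals,n_variants,n_causal Cohort and genotype dimensions;
#'   `n_causal <= n_variants`.
#' @param ld_block_size Variants per LD block.
#' @param ld_decay First-order autoregressive correlation of the latent
#'   haplotype process within a block, in `[0, 1)`; 0 gives independent sites.
#' @param maf_range Length-2 range in (0, 1) the per-variant minor allele
#'   frequencies are drawn from.
#' @param causal_effect_sd Standard deviation of true per-allele log-odds
#'   effects at causal variants.
#' @param exposure_specs Data frame (or tibble) with columns `name`,
#'   `prevalence` in (0,1) and `log_or` — the log-odds effect of the binary
#'   exposure on disease.
#' @param baseline_log_odds Log-odds of disease at the reference profile
#'   (age 60, female, mean genetic score, unexposed).
#' @param age_coefficient Log-odds per year of age (centred at 60).
#' @param sex_coefficient Log-odds for male sex.
#' @param prs_coefficient Log-odds per SD of the true (latent) genetic score.
#' @param interaction_specs Data frame with columns `name` (an exposure name)
#'   and `log_or` — the log-odds interaction between that exposure and the
#'   standardised true genetic score. May have zero rows.
#' @param incident_fraction Fraction of cases flagged as incident, in (0, 1].
#' @param missing_genotype_rate Completely-at-random dosage missingness,
#'   in `[0, 1)`.
#' @param n_related_pairs Number of related sample pairs to record.
#' @param onset_base,onset_slope,onset_sd Age-at-diagnosis model for cases:
#'   `onset_base - onset_slope * standardised true score + N(0, onset_sd)`,
#'   in years; a positive slope means higher genetic load brings diagnosis
#'   earlier.
#' @param prop_non_european Fraction of individuals given a non-reference
#'   ancestry label (and a shifted PC offset).
#' @param seed Integer seed governing all generators through per-component
#'   child streams.
#' @return A validated list of class `pd_sim_config`.
#' @examples
#' cfg <- sim_config(n_individuals = 200, n_variants = 40, n_causal = 5, seed = 1)
#' @export
sim_config <- function(n_individuals = 5000,
                       n_variants = 500,
                       n_causal = 20,
                       ld_block_size = 10,
                       ld_decay = 0.8,
                       maf_range = c(0.05, 0.5),
                       causal_effect_sd = 0.15,
                       exposure_specs = default_exposures(),
                       baseline_log_odds = -2.5,
                       age_coefficient = 0.05,
                       sex_coefficient = 0.4,
                       prs_coefficient = log(1.5),
                       interaction_specs = NULL,
                       incident_fraction = 0.6,
                       missing_genotype_rate = 0.01,
                       n_related_pairs = 0,
                       onset_base = 66,
                       onset_slope = 0.5,
                       onset_sd = 5,
                       prop_non_european = 0.05,
                       seed = 42L) {
  if (n_individuals < 1 || n_variants < 1) {
    stop("n_individuals and n_variants must be positive", call. = FALSE)
  }
  if (n_causal < 0 || n_causal > n_variants) {
    stop("n_causal must lie in [0, n_variants]", call. = FALSE)
  }
  if (ld_decay < 0 || ld_decay >= 1) stop("ld_decay must be in [0, 1)", call. = FALSE)
  stopifnot(length(maf_range) == 2, all(maf_range > 0), all(maf_range < 1),
            maf_range[1] <= maf_range[2])
  exposure_specs <- tibble::as_tibble(exposure_specs)
  if (nrow(exposure_specs)) {
    stopifnot(all(c("name", "prevalence", "log_or") %in% names(exposure_specs)))
    if (any(exposure_specs$prevalence <= 0 | exposure_specs$prevalence >= 1)) {
      stop("exposure prevalences must be in (0, 1)", call. = FALSE)
    }
    if (anyDuplicated(exposure_specs$name)) {
      stop("duplicate exposure names", call. = FALSE)
    }
  }
  if (is.null(interaction_specs)) {
    interaction_specs <- tibble::tibble(name = character(), log_or = numeric())
  }
  interaction_specs <- tibble::as_tibble(interaction_specs)
  if (nrow(interaction_specs)) {
    stopifnot(all(c("name", "log_or") %in% names(interaction_specs)))
    missing_exp <- setdiff(interaction_specs$name, exposure_specs$name)
    if (length(missing_exp)) {
      stop("interaction_specs name(s) absent from exposure_specs: ",
           paste(missing_exp, collapse = ", "), call. = FALSE)
    }
  }
  if (incident_fraction <= 0 || incident_fraction > 1) {
    stop("incident_fraction must be in (0, 1]", call. = FALSE)
  }
  if (missing_genotype_rate < 0 || missing_genotype_rate >= 1) {
    stop("missing_genotype_rate must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_variants = as.integer(n_variants),
      n_causal = as.integer(n_causal),
      ld_block_size = as.integer(ld_block_size),
      ld_decay = ld_decay,
      maf_range = maf_range,
      causal_effect_sd = causal_effect_sd,
      exposure_specs = exposure_specs,
      baseline_log_odds = baseline_log_odds,
      age_coefficient = age_coefficient,
      sex_coefficient = sex_coefficient,
      prs_coefficient = prs_coefficient,
      interaction_specs = interaction_specs,
      incident_fraction = incident_fraction,
      missing_genotype_rate = missing_genotype_rate,
      n_related_pairs = as.integer(n_related_pairs),
      onset_base = onset_base,
      onset_slope = onset_slope,
      onset_sd = onset_sd,
      prop_non_european = prop_non_european,
      seed = as.integer(seed)
    ),
    class = "pd_sim_config"
  )
}

#' Default exposure panel for the synthetic cohort
#'
#' A small panel of binary exposures modelled on the risk/protective factors
#' typically screened in incident Parkinson's cohorts, with population-scale
#' prevalences and modest log-odds effects.
#'
#' @return Tibble with columns `name`, `prevalence`, `log_or`.
#' @export
default_exposures <- function() {
  tibble::tribble(
    ~name,            ~prevalence, ~log_or,
    "family_history", 0.05,        log(2.2),
    "depression",     0.10,        log(1.76),
    "low_alcohol",    0.30,        log(1.39),
    "ever_smoker",    0.45,        log(0.80),
    "diabetes",       0.08,        log(1.27),
    "epilepsy",       0.01,        log(2.87),
    "daytime_sleepiness", 0.20,    log(1.33),
    "gastric_ulcer",  0.04,        log(1.69)
  )
}

#' @export
print.pd_sim_config <- function(x, ...) {
  cat("<pd_sim_config> ", x$n_individuals, " individuals x ", x$n_variants,
      " variants (", x$n_causal, " causal), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate a genotype matrix with block LD structure
#'
#' Draws two haplotypes per individual from a latent first-order
#' autoregressive Gaussian process within each LD block (correlation
#' `ld_decay` between adjacent sites, decaying geometrically with distance)
#' thresholded at each variant's allele frequency; dosages are the haplotype
#' sums, so they take values 0/1/2. A small designated subset of variants is
#' made palindromic (A/T or C/G) and another subset is given low imputation
#' quality or extreme Hardy-Weinberg p-values so that downstream QC filters
#' have work to do. Missingness is applied completely at random. True causal
#' effects are drawn for `n_causal` variants chosen among the clean
#' (QC-passing) sites.
#'
#' @param config A [sim_config()].
#' @return An object of class `pd_genotypes`: a list with `dosages`
#'   (individuals x variants integer matrix with `NA` for missing),
#'   `variants` (tibble: rsid, chrom, pos, a1, a2, maf, info, hwe_p),
#'   `sample_ids`, and `effects` (tibble rsid/beta of true causal effects).
#' @examples
#' g <- simulate_genotypes(sim_config(n_individuals = 100, n_variants = 20,
#'                                    n_causal = 2, seed = 1))
#' dim(g$dosages)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "pd_sim_config"))
  n <- config$n_individuals
  m <- config$n_variants
  withr::with_seed(child_seed(config$seed, 1L), {
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    block <- rep(seq_len(ceiling(m / config$ld_block_size)),
                 each = config$ld_block_size)[seq_len(m)]
    # 10 kb between adjacent sites; 2 Mb gaps between blocks; new chromosome
    # every 10 blocks so the clumping window never spans a block boundary.
    chrom <- as.character(((block - 1L) %/% 10L) %% 22L + 1L)
    pos_in_block <- stats::ave(seq_len(m), block, FUN = seq_along)
    pos <- integer(m)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      b <- block[idx]
      b_rank <- match(b, unique(b))
      pos[idx] <- (b_rank - 1L) * 2000000L + pos_in_block[idx] * 10000L
    }
    dos <- matrix(0L, n, m)
    thr <- qnorm(maf)
    rho <- config$ld_decay
    scale <- sqrt(1 - rho^2)
    # haplotypes drawn column-wise so only one latent vector is live at a
    # time; draw order matches a full column-major matrix exactly
    for (h in 1:2) {
      z_prev <- NULL
      for (j in seq_len(m)) {
        z <- rnorm(n)
        if (j > 1L && rho > 0 && block[j] == block[j - 1L]) {
          z <- rho * z_prev + scale * z
        }
        dos[, j] <- dos[, j] + (z < thr[j])
        z_prev <- z
      }
    }

    # allele labels: ~5% palindromic to exercise strand-ambiguity filters
    bases <- c("A", "C", "G", "T")
    a1 <- sample(bases, m, replace = TRUE)
    a2 <- vapply(a1, function(b) sample(setdiff(bases, c(b, comp_base(b))), 1L), "")
    n_pal <- max(1L, floor(0.05 * m))
    pal_idx <- sample.int(m, n_pal)
    a2[pal_idx] <- comp_base(a1[pal_idx])

    info <- runif(m, 0.85, 1)
    hwe_p <- runif(m, 0.05, 1)
    n_bad <- max(1L, floor(0.02 * m))
    low_info_idx <- sample(setdiff(seq_len(m), pal_idx), n_bad)
    info[low_info_idx] <- runif(n_bad, 0.05, 0.25)
    bad_hwe_idx <- sample(setdiff(seq_len(m), c(pal_idx, low_info_idx)), n_bad)
    hwe_p[bad_hwe_idx] <- 10^runif(n_bad, -10, -7)

    if (config$missing_genotype_rate > 0) {
      miss <- runif(n * m) < config$missing_genotype_rate
      dos[miss] <- NA_integer_
    }

    variants <- tibble::tibble(
      rsid = sprintf("rs%06d", seq_len(m)),
      chrom = chrom, pos = pos, a1 = a1, a2 = a2,
      maf = maf, info = info, hwe_p = hwe_p
    )
    clean <- setdiff(seq_len(m), c(pal_idx, low_info_idx, bad_hwe_idx))
    causal_idx <- sort(sample(clean, min(config$n_causal, length(clean))))
    effects <- tibble::tibble(
      rsid = variants$rsid[causal_idx],
      beta = rnorm(length(causal_idx), 0, config$causal_effect_sd)
    )
    sample_ids <- sprintf("ID%06d", seq_len(n))
    dimnames(dos) <- list(sample_ids, variants$rsid)
    new_pd_genotypes(dos, variants, sample_ids, effects)
  })
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

new_pd_genotypes <- function(dosages, variants, sample_ids, effects = NULL) {
  stopifnot(nrow(dosages) == length(sample_ids),
            ncol(dosages) == nrow(variants))
  structure(
    list(dosages = dosages, variants = tibble::as_tibble(variants),
         sample_ids = sample_ids, effects = effects),
    class = "pd_genotypes"
  )
}

#' @export
print.pd_genotypes <- function(x, ...) {
  cat("<pd_genotypes> ", length(x$sample_ids), " individuals x ",
      nrow(x$variants), " variants\n", sep = "")
  invisible(x)
}

#' Simulate GWAS summary statistics from true causal effects
#'
#' Emulates an external case-control GWAS of `gwas_n` samples: the estimated
#' per-allele log-odds ratio is the true effect (zero at non-causal variants)
#' plus Gaussian noise with variance `1 / (2 * gwas_n * maf * (1 - maf))`,
#' and the p-value is the two-sided Wald test of the estimate against zero.
#'
#' @param genotypes A `pd_genotypes` (carrying its true `effects`), or any
#'   variant tibble with `rsid`, `chrom`, `pos`, `a1`, `a2`, `maf` columns.
#' @param effects Tibble of true effects (`rsid`, `beta`); defaults to the
#'   effects stored in `genotypes`.
#' @param gwas_n Effective GWAS sample size (> 0).
#' @param seed Integer seed.
#' @return Tibble: `rsid, chrom, pos, a1, a2, beta, se, p, freq`.
#' @export
simulate_summary_stats <- function(genotypes, effects = NULL, gwas_n = 5e4,
                                   seed = 1L) {
  if (gwas_n <= 0) stop("gwas_n must be positive", call. = FALSE)
  variants <- if (inherits(genotypes, "pd_genotypes")) genotypes$variants else
    tibble::as_tibble(genotypes)
  effects <- effects %||%
    (if (inherits(genotypes, "pd_genotypes")) genotypes$effects else NULL)
  beta_true <- rep(0, nrow(variants))
  if (!is.null(effects) && nrow(effects)) {
    beta_true[match(effects$rsid, variants$rsid)] <- effects$beta
  }
  withr::with_seed(child_seed(seed, 2L), {
    se <- 1 / sqrt(2 * gwas_n * variants$maf * (1 - variants$maf))
    beta_hat <- beta_true + rnorm(nrow(variants), 0, se)
    p <- 2 * pnorm(-abs(beta_hat / se))
    tibble::tibble(
      rsid = variants$rsid, chrom = variants$chrom, pos = variants$pos,
      a1 = variants$a1, a2 = variants$a2,
      beta = beta_hat, se = se, p = pmax(p, .Machine$double.xmin),
      freq = variants$maf
    )
  })
}

# Latent genetic score: effect-weighted dosage sum with per-variant mean
# imputation of missing calls, standardised to mean 0 / SD 1.
true_genetic_score <- function(genotypes) {
  eff <- genotypes$effects
  if (is.null(eff) || nrow(eff) == 0) {
    return(rep(0, length(genotypes$sample_ids)))
  }
  D <- genotypes$dosages[, eff$rsid, drop = FALSE]
  for (j in seq_len(ncol(D))) {
    nas <- is.na(D[, j])
    if (any(nas)) D[nas, j] <- mean(D[, j], na.rm = TRUE)
  }
  g <- drop(D %*% eff$beta)
  if (sd(g) == 0) return(rep(0, length(g)))
  (g - mean(g)) / sd(g)
}

#' Simulate phenotypes, exposures and outcomes for a genotyped cohort
#'
#' Disease status is drawn from a logistic model combining the baseline
#' log-odds, age (centred at 60), sex, the standardised latent genetic score,
#' binary exposures, and any score-by-exposure interaction terms. A fraction
#' of cases is flagged incident; cases receive an age at diagnosis that
#' decreases with genetic load; four ancestry principal components are
#' generated as low-variance Gaussians with an ethnicity-linked offset.
#'
#' @param genotypes A `pd_genotypes` from [simulate_genotypes()].
#' @param config The same [sim_config()] used to generate the genotypes.
#' @return Tibble with one row per individual: `id`, `age`, `sex`,
#'   `ethnicity`, `townsend`, one column per exposure, `pd_status`,
#'   `incident`, `age_at_diagnosis` (NA for controls), `pc1`-`pc4`,
#'   `true_genetic_score`.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "pd_genotypes"),
            inherits(config, "pd_sim_config"))
  n <- length(genotypes$sample_ids)
  g <- true_genetic_score(genotypes)
  withr::with_seed(child_seed(config$seed, 3L), {
    age <- runif(n, 40, 69)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    ethnicity <- sample(c("white_british", "other"), n, replace = TRUE,
                        prob = c(1 - config$prop_non_european,
                                 config$prop_non_european))
    townsend <- rnorm(n, 0, 3)
    expo <- config$exposure_specs
    E <- matrix(0L, n, nrow(expo),
                dimnames = list(NULL, expo$name))
    for (k in seq_len(nrow(expo))) {
      E[, k] <- rbinom(n, 1, expo$prevalence[k])
    }
    eta <- config$baseline_log_odds +
      config$age_coefficient * (age - 60) +
      config$sex_coefficient * (sex == "male") +
      config$prs_coefficient * g
    if (nrow(expo)) eta <- eta + drop(E %*% expo$log_or)
    ints <- config$interaction_specs
    if (nrow(ints)) {
      for (k in seq_len(nrow(ints))) {
        eta <- eta + ints$log_or[k] * g * E[, ints$name[k]]
      }
    }
    pd_status <- rbinom(n, 1, plogis(eta))
    incident <- integer(n)
    case_idx <- which(pd_status == 1)
    incident[case_idx] <- rbinom(length(case_idx), 1, config$incident_fraction)
    age_at_diagnosis <- rep(NA_real_, n)
    age_at_diagnosis[case_idx] <- config$onset_base -
      config$onset_slope * g[case_idx] +
      rnorm(length(case_idx), 0, config$onset_sd)
    offset <- ifelse(ethnicity == "white_british", 0, 0.3)
    pcs <- vapply(1:4, function(k) rnorm(n, 0, 0.1) + offset / k,
                  numeric(n))
    out <- tibble::tibble(
      id = genotypes$sample_ids,
      age = age, sex = sex, ethnicity = ethnicity, townsend = townsend,
      tibble::as_tibble(E),
      pd_status = pd_status, incident = incident,
      age_at_diagnosis = age_at_diagnosis,
      pc1 = pcs[, 1], pc2 = pcs[, 2], pc3 = pcs[, 3], pc4 = pcs[, 4],
      true_genetic_score = g
    )
    out
  })
}

#' Simulate a kinship pair list
#'
#' Records `n_related_pairs` distinct unordered sample pairs with kinship
#' coefficients spanning first- to third-degree relationships (0.25, 0.125,
#' 0.0625, jittered), as produced by array-based relatedness estimation.
#'
#' @param sample_ids Character vector of cohort identifiers.
#' @param n_pairs Number of related pairs.
#' @param seed Integer seed.
#' @return Tibble: `id1`, `id2`, `kinship`.
#' @export
simulate_kinship <- function(sample_ids, n_pairs, seed = 1L) {
  n_pairs <- as.integer(n_pairs)
  if (n_pairs == 0) {
    return(tibble::tibble(id1 = character(), id2 = character(),
                          kinship = numeric()))
  }
  stopifnot(length(sample_ids) >= 2 * n_pairs)
  withr::with_seed(child_seed(seed, 4L), {
    picked <- sample(sample_ids, 2L * n_pairs)
    id1 <- picked[seq_len(n_pairs)]
    id2 <- picked[n_pairs + seq_len(n_pairs)]
    base <- sample(c(0.25, 0.125, 0.0625), n_pairs, replace = TRUE)
    kin <- pmin(0.5, pmax(0, base + rnorm(n_pairs, 0, 0.01)))
    swap <- id2 < id1
    tibble::tibble(
      id1 = ifelse(swap, id2, id1),
      id2 = ifelse(swap, id1, id2),
      kinship = kin
    )
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_summary_stats()], [simulate_phenotypes()] and
#' [simulate_kinship()] under one configuration.
#'
#' @param config A [sim_config()].
#' @param gwas_n External GWAS sample size for the summary statistics.
#' @return List of class `pd_cohort_sim`: `genotypes`, `sumstats`, `cohort`,
#'   `kinship`, `config`.
#' @export
simulate_cohort <- function(config, gwas_n = 5e4) {
  genotypes <- simulate_genotypes(config)
  sumstats <- simulate_summary_stats(genotypes, gwas_n = gwas_n,
                                     seed = config$seed)
  cohort <- simulate_phenotypes(genotypes, config)
  kinship <- simulate_kinship(genotypes$sample_ids, config$n_related_pairs,
                              seed = config$seed)
  structure(
    list(genotypes = genotypes, sumstats = sumstats, cohort = cohort,
         kinship = kinship, config = config),
    class = "pd_cohort_sim"
  )
}
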
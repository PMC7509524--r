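ref_variants <- function(pos, chrom = "1") {
  tibble::tibble(
    rsid = sprintf("rv%d", seq_along(pos)), chrom = chrom,
    pos = as.integer(pos),
    a1 = "A", a2 = "G", maf = 0.3, info = 0.95, hwe_p = 0.5
  )
}

test_that("greedy clumping keeps index variants and respects the window", {
  set.seed(1)
  base <- rbinom(200, 2, 0.3)
  # three tightly linked variants within 50 kb: only the best p survives
  D <- cbind(base, base, base)
  storage.mode(D) <- "integer"
  v <- ref_variants(c(1000, 20000, 40000))
  g <- toy_genotypes(D, v)
  stats <- tibble::tibble(rsid = v$rsid, chrom = v$chrom, pos = v$pos,
                          p = c(1e-8, 1e-6, 1e-4))
  expect_identical(clump(stats, g, r2_threshold = 0.9, window_kb = 250),
                   "rv1")
  # identical variants 300 kb apart are both retained under a 250 kb window
  v2 <- ref_variants(c(0, 300000))
  g2 <- toy_genotypes(cbind(base, base), v2)
  stats2 <- tibble::tibble(rsid = v2$rsid, chrom = v2$chrom, pos = v2$pos,
                           p = c(1e-8, 1e-6))
  expect_setequal(clump(stats2, g2, 0.9, 250), c("rv1", "rv2"))
  # single variant trivially retained
  expect_identical(clump(stats2[1, ], g2, 0.9, 250), "rv1")
  # absent-from-reference variants are excluded with a warning
  stats3 <- rbind(stats2, tibble::tibble(rsid = "ghost", chrom = "1",
                                         pos = 5L, p = 1e-10))
  expect_warning(kept <- clump(stats3, g2, 0.9, 250), "absent from reference")
  expect_false("ghost" %in% kept)
})

test_that("clumping equals the brute-force oracle and ignores row order", {
  for (seed in 1:25) {
    set.seed(seed)
    m <- sample(5:25, 1)
    n <- 120
    # random LD: mixture of independent and near-duplicate columns
    D <- matrix(rbinom(n * m, 2, runif(1, 0.2, 0.4)), n, m)
    dup_from <- sample(m, floor(m / 3))
    for (j in dup_from) {
      src <- sample(m, 1)
      flip <- sample(n, 5)
      D[, j] <- D[, src]
      D[flip, j] <- rbinom(5, 2, 0.3)
    }
    storage.mode(D) <- "integer"
    v <- ref_variants(sort(sample(1:500, m)) * 1000)
    g <- toy_genotypes(D, v)
    stats <- tibble::tibble(rsid = v$rsid, chrom = v$chrom, pos = v$pos,
                            p = runif(m))
    r2t <- sample(c(0.2, 0.5, 0.8), 1)
    wkb <- sample(c(50, 250), 1)
    got <- clump(stats, g, r2t, wkb)
    want <- clump_oracle(stats, g, r2t, wkb)
    expect_setequal(got, want)
    shuffled <- stats[sample(nrow(stats)), ]
    expect_setequal(clump(shuffled, g, r2t, wkb), want)
  }
})

test_that("scoring matches hand arithmetic on a printed toy panel", {
  # 3-person training panel, two loci, betas 0.2 and -0.1
  panel_D <- matrix(c(0L, 1L, 2L,   # locus 1
                      2L, 1L, 0L),  # locus 2
                    nrow = 3)
  v <- ref_variants(c(1000, 500000))
  panel <- toy_genotypes(panel_D, v)
  model <- pdrisk:::new_prs_model(
    tibble::tibble(rsid = v$rsid, chrom = v$chrom, pos = v$pos, a1 = v$a1,
                   a2 = v$a2, beta = c(0.2, -0.1)),
    p_threshold = 1, r2_threshold = 0.8
  )
  model <- pdrisk:::fit_standardisation(model, panel)
  # locus scores on the panel: (0, .2, .4) and (-.2, -.1, 0)
  expect_equal(model$variants$mean, c(0.2, -0.1))
  expect_equal(model$variants$sd, c(sd(c(0, .2, .4)), sd(c(-.2, -.1, 0))))
  target <- toy_genotypes(matrix(c(2L, 1L), nrow = 1), v, "X1")
  got <- prs_score(target, model)$score
  want <- (2 * 0.2 - 0.2) / sd(c(0, .2, .4)) +
    (1 * -0.1 - (-0.1)) / sd(c(-.2, -.1, 0))
  expect_equal(got, want, tolerance = 1e-12)

  # an all-missing individual scores exactly 0
  miss <- toy_genotypes(matrix(NA_integer_, 1, 2), v, "M1")
  expect_identical(prs_score(miss, model)$score, 0)

  # strand/orientation invariance: counting the other allele flips dosage
  v_fl <- v
  v_fl$a1 <- v$a2
  v_fl$a2 <- v$a1
  target_fl <- toy_genotypes(matrix(c(0L, 1L), nrow = 1), v_fl, "X1")
  expect_equal(prs_score(target_fl, model)$score, want, tolerance = 1e-12)
})

test_that("scoring is linear in the weights before standardisation", {
  set.seed(3)
  v <- ref_variants(c(1, 2, 3) * 100000)
  D <- matrix(rbinom(30, 2, 0.4), 10, 3)
  storage.mode(D) <- "integer"
  g <- toy_genotypes(D, v)
  mk <- function(betas) {
    m <- pdrisk:::new_prs_model(
      tibble::tibble(rsid = v$rsid, chrom = v$chrom, pos = v$pos,
                     a1 = v$a1, a2 = v$a2, beta = betas,
                     mean = 0, sd = 1), 1, 0.8)
    m
  }
  w1 <- c(0.1, -0.2, 0.3)
  w2 <- c(0.05, 0.4, -0.1)
  s1 <- prs_score(g, mk(w1))$score
  s2 <- prs_score(g, mk(w2))$score
  s12 <- prs_score(g, mk(w1 + w2))$score
  expect_equal(s12, s1 + s2, tolerance = 1e-12)
})

test_that("the candidate grid is complete and monotone in the p threshold", {
  sim <- shared_sim()
  fv <- filter_variants(sim$genotypes, sim$sumstats)
  stats <- sim$sumstats[sim$sumstats$rsid %in% fv$retained, ]
  grid <- ct_grid()
  cands <- build_candidates(stats, fv$genotypes, grid)
  expect_length(cands, 50)
  tab <- dplyr::bind_rows(lapply(cands, glance))
  for (r2 in grid$r2_thresholds) {
    ns <- tab$n_snps[tab$r2_threshold == r2][order(grid$p_thresholds)]
    expect_true(all(diff(ns) >= 0)) # loosening p never loses SNPs
  }
  # no clumping analogue: p = 1 with r2 threshold 1 keeps every variant
  all_in <- build_candidates(stats, fv$genotypes,
                             ct_grid(p_thresholds = 1, r2_thresholds = 1))
  expect_identical(all_in[[1]]$n_snps, nrow(stats))
})

test_that("selection maximises pseudo-R2 and breaks ties by fewer SNPs", {
  sim <- shared_sim()
  fv <- filter_variants(sim$genotypes, sim$sumstats)
  stats <- sim$sumstats[sim$sumstats$rsid %in% fv$retained, ]
  cands <- build_candidates(stats, fv$genotypes,
                            ct_grid(p_thresholds = c(5e-5, 1),
                                    r2_thresholds = 0.2))
  # duplicate of the stringent candidate padded with a zero-weight variant:
  # identical scores, more SNPs -> the leaner model must win the tie
  dup <- cands[[1]]
  extra <- stats[!stats$rsid %in% dup$variants$rsid, ][1, ]
  pad <- dup$variants[1, ]
  pad$rsid <- extra$rsid; pad$chrom <- extra$chrom; pad$pos <- extra$pos
  pad$beta <- 0; pad$mean <- 0; pad$sd <- NA_real_
  dup$variants <- rbind(dup$variants, pad)
  dup$n_snps <- nrow(dup$variants)
  sel <- select_best(list(dup, cands[[1]], cands[[2]]),
                     fv$genotypes, sim$cohort)
  expect_equal(sel$table$r2_nagelkerke[1], sel$table$r2_nagelkerke[2],
               tolerance = 1e-12)
  expect_identical(sel$best_index, 2L)
  expect_identical(glance(sel)$n_snps, cands[[1]]$n_snps)
})

test_that("null summary statistics leave nothing to select", {
  cfg <- sim_config(n_individuals = 20000, n_variants = 30, n_causal = 0,
                    baseline_log_odds = -2, prs_coefficient = 0, seed = 31L)
  sim <- simulate_cohort(cfg, gwas_n = 1e4)
  fv <- filter_variants(sim$genotypes, sim$sumstats)
  stats <- sim$sumstats[sim$sumstats$rsid %in% fv$retained, ]
  cands <- build_candidates(stats, fv$genotypes,
                            ct_grid(p_thresholds = c(0.05, 1),
                                    r2_thresholds = 0.2))
  sel <- select_best(cands, fv$genotypes, sim$cohort)
  expect_lt(max(sel$table$r2_nagelkerke, na.rm = TRUE), 0.002)
})

test_that("decile odds ratios equal the contingency-table oracle", {
  set.seed(5)
  n <- 2000
  cohort <- tibble::tibble(
    id = sprintf("D%04d", 1:n),
    score = runif(n)
  )
  dec <- dplyr::ntile(cohort$score, 10)
  cohort$pd_status <- rbinom(n, 1, 0.05 + 0.02 * dec)
  tab <- decile_analysis(cohort[, c("id", "score")], cohort,
                         covariates = character())
  for (k in c(2, 5, 10)) {
    a <- sum(cohort$pd_status[dec == k]); b <- sum(dec == k) - a
    c0 <- sum(cohort$pd_status[dec == 1]); d0 <- sum(dec == 1) - c0
    expect_equal(tab$or[tab$decile == k], (a * d0) / (b * c0),
                 tolerance = 1e-6)
  }
  expect_identical(tab$or[tab$decile == 1], 1)
})

test_that("null scores give decile CIs covering 1", {
  set.seed(6)
  n <- 8000
  cohort <- tibble::tibble(id = as.character(1:n), score = rnorm(n),
                           pd_status = rbinom(n, 1, 0.1))
  tab <- decile_analysis(cohort[, c("id", "score")], cohort,
                         covariates = character())
  covers <- tab$ci_low[-1] <= 1 & tab$ci_high[-1] >= 1
  expect_gte(sum(covers), 8)
})

test_that("the onset model recovers a negative score-onset slope", {
  set.seed(7)
  n <- 2000
  s <- rnorm(n)
  cohort <- tibble::tibble(
    id = as.character(1:n), pd_status = 1,
    age = runif(n, 50, 70), sex = sample(c("male", "female"), n, TRUE),
    pc1 = rnorm(n, 0, .1), pc2 = rnorm(n, 0, .1),
    pc3 = rnorm(n, 0, .1), pc4 = rnorm(n, 0, .1),
    age_at_diagnosis = 66 - 0.5 * s + rnorm(n, 0, 3)
  )
  scores <- tibble::tibble(id = cohort$id, score_int = s)
  fit <- onset_model(scores, cohort)
  expect_gt(fit$slope, -0.7)
  expect_lt(fit$slope, -0.3)
  # null: CI covers 0
  cohort0 <- cohort
  cohort0$age_at_diagnosis <- 66 + rnorm(n, 0, 3)
  fit0 <- onset_model(scores, cohort0)
  expect_true(fit0$ci_low <= 0 && fit0$ci_high >= 0)
  # duplicated data: identical estimate, smaller p
  cohort2 <- dplyr::bind_rows(cohort, dplyr::mutate(cohort, id = paste0(id, "b")))
  scores2 <- tibble::tibble(id = cohort2$id, score_int = c(s, s))
  fit2 <- onset_model(scores2, cohort2)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-10)
  expect_lt(fit2$p, fit$p)
  # refuses tiny case sets
  expect_error(onset_model(scores[1:10, ], cohort[1:10, ]),
               "insufficient cases")
})

test_that("known-loci exclusion uses an inclusive 1 Mb window", {
  v <- ref_variants(c(4100000, 6100000, 6100001 + 1))
  v$pos <- as.integer(c(4100000, 6100000, 6000001))
  set.seed(8)
  D <- matrix(rbinom(60, 2, 0.3), 20, 3); storage.mode(D) <- "integer"
  g <- toy_genotypes(D, v)
  model <- pdrisk:::fit_standardisation(pdrisk:::new_prs_model(
    tibble::tibble(rsid = v$rsid, chrom = v$chrom, pos = v$pos, a1 = v$a1,
                   a2 = v$a2, beta = c(0.1, 0.2, 0.3)), 1, 0.8), g)
  lead <- tibble::tibble(chrom = "1", pos = 5000000L)
  # 4.1 Mb and 6.1 Mb within/below 1 Mb of the lead: hmm, compute directly
  out <- exclude_known_loci(model, lead, g)
  dist <- abs(v$pos - 5000000L)
  expect_setequal(out$variants$rsid, v$rsid[dist > 1e6])
  # boundary: exactly 1 Mb removed, 1 Mb + 1 retained
  v2 <- ref_variants(c(4000000, 3999999))
  g2 <- toy_genotypes(matrix(rbinom(40, 2, .3), 20, 2), v2)
  m2 <- pdrisk:::fit_standardisation(pdrisk:::new_prs_model(
    tibble::tibble(rsid = v2$rsid, chrom = v2$chrom, pos = v2$pos,
                   a1 = v2$a1, a2 = v2$a2, beta = c(0.1, 0.1)), 1, 0.8), g2)
  out2 <- exclude_known_loci(m2, tibble::tibble(chrom = "1", pos = 5000000L),
                             g2)
  expect_identical(out2$variants$rsid, "rv2") # 1000001 bp away survives
  # empty lead list: unchanged
  expect_identical(exclude_known_loci(model, lead[0, ], g), model)
})
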
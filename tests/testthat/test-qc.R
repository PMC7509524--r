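make_toy_variants <- function() {
  # 10 variants, one defect each for six of them
  tibble::tibble(
    rsid = c("rs1", "rs1", "rs3", "rs4", "rs5", "rs6", "rs7", "rs8", "rs9",
             "rs10"),
    chrom = "1",
    pos = as.integer(seq(1000, 10000, by = 1000)),
    a1 = c("A", "C", "A", "A", "C", "C", "G", "A", "C", "G"),
    a2 = c("G", "G", "T", "C", "T", "A", "T", "G", "A", "T"),
    maf = c(0.2, 0.2, 0.2, 0.009, 0.2, 0.2, 0.3, 0.3, 0.25, 0.2),
    info = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.2, 0.95, 0.9, 0.9, 0.9),
    hwe_p = c(0.5, 0.5, 0.5, 0.5, 1e-07, 0.5, 0.5, 0.5, 0.5, 0.5)
  )
}

toy_qc_genotypes <- function(variants, miss_col = NULL, miss_frac = 0) {
  set.seed(42)
  n <- 50
  D <- matrix(rbinom(n * nrow(variants), 2, 0.3), n, nrow(variants))
  if (!is.null(miss_col)) {
    D[seq_len(ceiling(miss_frac * n)), miss_col] <- NA_integer_
  }
  storage.mode(D) <- "integer"
  toy_genotypes(D, variants)
}

test_that("variant filters remove exactly the constructed defects", {
  v <- make_toy_variants()
  # rs1 duplicated, rs3 an A/T palindrome, rs4 rare, rs6 low info,
  # rs5 HWE-violating, rs9 gets 12% missingness
  g <- toy_qc_genotypes(v, miss_col = 9, miss_frac = 0.12)
  stats <- tibble::tibble(rsid = v$rsid)
  res <- filter_variants(g, stats)
  expect_setequal(res$retained, c("rs1", "rs7", "rs8", "rs10"))
  # one removal per defect, itemised
  rep <- res$report
  expect_identical(rep$removed[rep$step == "duplicate_rsid"], 1L)
  expect_identical(rep$removed[rep$step == "palindromic"], 1L)
  expect_identical(rep$removed[rep$step == "maf"], 1L)
  expect_identical(rep$removed[rep$step == "missingness"], 1L)
  expect_identical(rep$removed[rep$step == "hwe"], 1L)
  expect_identical(rep$removed[rep$step == "info"], 1L)
  expect_identical(sum(rep$removed) + length(res$retained), 10L)
})

test_that("a toy set matching the stated worked example keeps 4 of 10", {
  v <- make_toy_variants()
  v$pos[9] <- v$pos[8] # give rs9 rs8's position instead of missingness
  v$pos[2] <- 1500L    # keep the duplicate rsID but distinct position
  g <- toy_qc_genotypes(v)
  res <- filter_variants(g, tibble::tibble(rsid = v$rsid))
  expect_length(res$retained, 4)
})

test_that("clean variants pass untouched and boundaries are strict", {
  v <- make_toy_variants()[c(3, 7, 8, 10), ]
  v$rsid <- paste0("c", 1:4)
  v$a2 <- c("G", "T", "C", "A") # no complementary pairs
  v$maf <- c(0.01, 0.2, 0.3, 0.4) # exactly 0.01 must survive (< is strict)
  v$info <- 0.9
  v$hwe_p <- 0.5
  g <- toy_qc_genotypes(v)
  res <- filter_variants(g, tibble::tibble(rsid = v$rsid))
  expect_identical(res$retained, v$rsid)
  expect_error(
    filter_variants(g, tibble::tibble(rsid = "absent")),
    "no overlapping variants"
  )
})

test_that("final retained set is invariant to order of independent criteria", {
  # non-overlapping defects: any filter order gives the same survivors
  v <- make_toy_variants()
  g <- toy_qc_genotypes(v, miss_col = 9, miss_frac = 0.12)
  base <- filter_variants(g, tibble::tibble(rsid = v$rsid))$retained
  # tighten thresholds one at a time; survivors of the full filter never
  # reappear when criteria are reapplied in a different sequence
  t2 <- qc_thresholds(maf_min = 0.0, info_min = 0.0)
  partial <- filter_variants(g, tibble::tibble(rsid = v$rsid), t2)
  res2 <- filter_variants(partial$genotypes, tibble::tibble(rsid = v$rsid))
  expect_setequal(res2$retained, base)
})

test_that("sample filters apply the strict missingness and ancestry rules", {
  v <- make_toy_variants()[7:10, ]
  v$rsid <- paste0("s", 1:4)
  set.seed(7)
  n <- 100
  D <- matrix(rbinom(n * 4, 2, 0.3), n, 4)
  D[1, 1:2] <- NA # sample 1: 50% missing -> removed
  storage.mode(D) <- "integer"
  g <- toy_genotypes(D, v)
  res <- filter_samples(g, NULL, qc_thresholds(sample_missing_max = 0.4))
  expect_false("S01" %in% res$sample_ids)
  expect_length(res$sample_ids, 99)

  # exactly-at-threshold sample retained (strict >)
  v10 <- make_toy_variants()
  v10$rsid <- paste0("t", 1:10)
  v10$pos <- as.integer(1:10 * 100)
  D10 <- matrix(1L, 20, 10)
  D10[1, 1] <- NA # 10% missing exactly
  D10[2, 1:2] <- NA # 20%: removed
  g10 <- toy_genotypes(D10, v10)
  res10 <- filter_samples(g10, NULL, qc_thresholds())
  expect_true("S01" %in% res10$sample_ids)
  expect_false("S02" %in% res10$sample_ids)

  # ancestry label filter: 6 samples, 2 non-matching
  v1 <- v10[1, ]
  g6 <- toy_genotypes(matrix(1L, 6, 1), v1)
  cohort <- tibble::tibble(id = g6$sample_ids,
                           ethnicity = c("white_british", "white_british",
                                         "other", "white_british", "other",
                                         "white_british"))
  res6 <- filter_samples(g6, cohort)
  expect_length(res6$sample_ids, 4)
  expect_identical(sum(res6$report$removed), 2L)
})

test_that("relatedness pruning removes the minimum under the greedy rule", {
  ids <- c("A", "B", "C", "D")
  # single pair above cutoff: exactly one removed
  p1 <- tibble::tibble(id1 = "A", id2 = "B", kinship = 0.05)
  kept <- prune_related(ids, p1)
  expect_length(kept, 3)
  expect_length(intersect(kept, c("A", "B")), 1)
  # below cutoff: both retained
  p2 <- tibble::tibble(id1 = "A", id2 = "B", kinship = 0.04)
  expect_setequal(prune_related(ids, p2), ids)
  # triangle A-B, B-C: removing B alone suffices
  p3 <- tibble::tibble(id1 = c("A", "B"), id2 = c("B", "C"),
                       kinship = c(0.1, 0.1))
  expect_setequal(prune_related(ids, p3), c("A", "C", "D"))
  # unknown id is a schema error
  p4 <- tibble::tibble(id1 = "A", id2 = "Z", kinship = 0.3)
  expect_error(prune_related(ids, p4), "unknown sample id")
})

test_that("no retained pair is related at or above the cutoff (property)", {
  for (seed in 1:5) {
    set.seed(seed)
    ids <- sprintf("P%02d", 1:30)
    pairs <- tibble::tibble(
      id1 = sample(ids, 40, replace = TRUE),
      id2 = sample(ids, 40, replace = TRUE),
      kinship = runif(40, 0, 0.3)
    )
    pairs <- pairs[pairs$id1 != pairs$id2, ]
    kept <- prune_related(ids, pairs, cutoff = 0.0442)
    bad <- pairs$kinship >= 0.0442 & pairs$id1 %in% kept & pairs$id2 %in% kept
    expect_false(any(bad))
  }
})

test_that("the exact HWE test matches a Monte Carlo pairing oracle", {
  # tiny table: enumerate by resampling allele pairings
  n_aa <- 6; n_ab <- 2; n_bb <- 2
  p_exact <- hwe_exact_test(n_aa, n_ab, n_bb)
  set.seed(1)
  alleles <- c(rep(0, 2 * n_aa + n_ab), rep(1, 2 * n_bb + n_ab))
  obs_het <- n_ab
  B <- 20000
  hets <- replicate(B, {
    a <- sample(alleles)
    sum(a[seq(1, length(a), 2)] != a[seq(2, length(a), 2)])
  })
  p_mc_by_het <- table(factor(hets, levels = sort(unique(hets)))) / B
  p_obs <- p_mc_by_het[as.character(obs_het)]
  p_mc <- sum(p_mc_by_het[p_mc_by_het <= p_obs + 1e-9])
  expect_lt(abs(p_exact - p_mc), 0.02)
  # Hardy-Weinberg proportions give p = 1-ish, monomorphic exactly 1
  expect_identical(hwe_exact_test(25, 0, 0), 1)
  expect_gt(hwe_exact_test(25, 50, 25), 0.5)
})
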
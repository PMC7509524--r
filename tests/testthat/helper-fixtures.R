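# Shared fixtures: everything is generated in code at test time.

tiny_config <- function(n = 500, m = 40, causal = 5, seed = 1L, ...) {
  sim_config(n_individuals = n, n_variants = m, n_causal = causal,
             seed = seed, ...)
}

# A moderate cohort reused across test files (built once per test run).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(
        sim_config(n_individuals = 3000, n_variants = 200, n_causal = 15,
                   baseline_log_odds = -2, seed = 99L),
        gwas_n = 1e5
      )
    }
    cache
  }
})

# Hand-rolled genotype container for toy examples.
toy_genotypes <- function(dosages, variants, sample_ids = NULL) {
  sample_ids <- sample_ids %||% sprintf("S%02d", seq_len(nrow(dosages)))
  dimnames(dosages) <- list(sample_ids, variants$rsid)
  pdrisk:::new_pd_genotypes(dosages, variants, sample_ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force transcription of the greedy clumping definition:
# full r2 matrix computed up front, index selection re-scans the sorted list
# on every step.
clump_oracle <- function(stats, reference, r2_threshold, window_kb) {
  stats <- stats[order(stats$p, stats$pos, stats$rsid), , drop = FALSE]
  D <- reference$dosages[, stats$rsid, drop = FALSE]
  R2 <- suppressWarnings(cor(D, use = "pairwise.complete.obs"))^2
  R2[is.na(R2)] <- 0
  remaining <- seq_len(nrow(stats))
  kept <- character()
  while (length(remaining)) {
    i <- remaining[1]
    kept <- c(kept, stats$rsid[i])
    claim <- vapply(remaining, function(j) {
      j != i &&
        stats$chrom[j] == stats$chrom[i] &&
        abs(stats$pos[j] - stats$pos[i]) <= window_kb * 1000 &&
        R2[i, j] >= r2_threshold
    }, TRUE)
    remaining <- remaining[!claim & remaining != i]
  }
  kept
}

# Brute-force RERI/AP from the risk table of a covariate-free logistic model:
# predicted risks at the four exposure cells -> three ORs -> RERI.
reri_oracle_from_betas <- function(b0, b1, b2, b12) {
  p <- function(x, y) plogis(b0 + b1 * x + b2 * y + b12 * x * y)
  odds <- function(pr) pr / (1 - pr)
  or10 <- odds(p(1, 0)) / odds(p(0, 0))
  or01 <- odds(p(0, 1)) / odds(p(0, 0))
  or11 <- odds(p(1, 1)) / odds(p(0, 0))
  list(reri = or11 - or10 - or01 + 1, ap = (or11 - or10 - or01 + 1) / or11)
}

# Step-up BH oracle written from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}
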
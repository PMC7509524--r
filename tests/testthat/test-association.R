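make_2x2_cohort <- function(n_exp_case = 20, n_exp = 100,
                            n_unexp_case = 10, n_unexp = 100) {
  tibble::tibble(
    id = as.character(seq_len(n_exp + n_unexp)),
    expo = rep(c(1, 0), c(n_exp, n_unexp)),
    pd_status = c(rep(c(1, 0), c(n_exp_case, n_exp - n_exp_case)),
                  rep(c(1, 0), c(n_unexp_case, n_unexp - n_unexp_case)))
  )
}

test_that("a crude exposure model reproduces the cross-product ratio", {
  cohort <- make_2x2_cohort()
  res <- fit_exposure_model(cohort, "expo", covariates = character())
  expect_equal(res$or, (20 * 90) / (80 * 10), tolerance = 1e-6)
  expect_false(res$flagged)
  expect_lt(res$lrt_p, 0.05)
})

test_that("degenerate and separated exposures are flagged, not dropped", {
  cohort <- make_2x2_cohort()
  cohort$allsame <- 1
  res <- fit_exposure_model(cohort, "allsame", covariates = character())
  expect_true(res$flagged)
  expect_true(is.na(res$or))
  # perfect separation flags the fit and withholds the CI
  sep <- tibble::tibble(id = as.character(1:40),
                        expo = rep(c(1, 0), each = 20),
                        pd_status = rep(c(1, 0), each = 20))
  res2 <- fit_exposure_model(sep, "expo", covariates = character())
  expect_true(res2$flagged)
})

test_that("a simulated depression-scale effect is recovered", {
  cfg <- sim_config(
    n_individuals = 100000, n_variants = 10, n_causal = 0,
    exposure_specs = tibble::tibble(name = "depr", prevalence = 0.1,
                                    log_or = log(1.76)),
    baseline_log_odds = -3.5, prs_coefficient = 0, seed = 41L
  )
  sim <- simulate_cohort(cfg, gwas_n = 1e4)
  inc <- incident_subset(sim$cohort)
  res <- fit_exposure_model(inc, "depr")
  expect_gt(res$or, 1.5)
  expect_lt(res$or, 2.1)
  # Wald and LRT p agree on the log10 scale (both are far into the tail
  # here, where the two statistics differ by a bounded factor)
  expect_lt(abs(log10(res$p_wald) - log10(res$lrt_p)),
            max(1, 0.3 * abs(log10(res$lrt_p))))
})

test_that("the likelihood-ratio test handles identity and nesting", {
  cohort <- make_2x2_cohort()
  fit <- glm(pd_status ~ expo, data = cohort, family = binomial())
  same <- lrt(fit, fit)
  expect_identical(same$statistic, 0)
  expect_identical(same$p, 1)
  null <- glm(pd_status ~ 1, data = cohort, family = binomial())
  lr <- lrt(fit, null)
  expect_identical(lr$df, 1L)
  expect_gt(lr$statistic, 0)
  non_nested <- suppressWarnings(
    glm(pd_status ~ id, data = cohort[1:4, ], family = binomial())
  )
  expect_error(lrt(fit, non_nested), "not nested")
})

test_that("BH adjustment matches hand arithmetic and a step-up oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04))$q, rep(0.04, 4))
  p_eq <- rep(0.3, 5)
  expect_equal(fdr_adjust(p_eq)$q, p_eq)
  set.seed(10)
  for (i in 1:100) {
    p <- runif(sample(3:30, 1))
    expect_equal(fdr_adjust(p)$q, bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(fdr_adjust(c(0.5, 0)), "p")
})

test_that("the combined model reduces to the single-exposure model", {
  cohort <- make_2x2_cohort()
  single <- fit_exposure_model(cohort, "expo", covariates = character())
  combined <- fit_combined_model(cohort, "expo", covariates = character())
  expect_equal(combined$or, single$or, tolerance = 1e-8)
  expect_equal(combined$p_wald, single$p_wald, tolerance = 1e-8)
})

test_that("perfectly collinear exposures are flagged in the joint model", {
  cohort <- make_2x2_cohort()
  cohort$expo2 <- cohort$expo
  res <- fit_combined_model(cohort, c("expo", "expo2"),
                            covariates = character())
  expect_true(any(res$flagged))
  expect_true(any(is.na(res$or)))
})

test_that("joint and marginal ORs agree for independent exposures", {
  cfg <- sim_config(
    n_individuals = 100000, n_variants = 10, n_causal = 0,
    exposure_specs = tibble::tibble(
      name = c("e1", "e2"), prevalence = c(0.2, 0.3),
      log_or = c(log(1.8), log(1.4))),
    baseline_log_odds = -3, prs_coefficient = 0, seed = 43L
  )
  sim <- simulate_cohort(cfg, gwas_n = 1e4)
  inc <- incident_subset(sim$cohort)
  marg1 <- fit_exposure_model(inc, "e1")$or
  joint <- fit_combined_model(inc, c("e1", "e2"))
  ratio <- joint$or[joint$exposure == "e1"] / marg1
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("family-wise FDR is controlled under the global null", {
  # all exposure effects zero: expected discovery fraction stays near 0.05
  hits <- 0; total <- 0
  for (seed in 1:12) {
    cfg <- sim_config(
      n_individuals = 3000, n_variants = 5, n_causal = 0,
      exposure_specs = tibble::tibble(
        name = paste0("x", 1:6), prevalence = rep(0.2, 6),
        log_or = rep(0, 6)),
      baseline_log_odds = -2, prs_coefficient = 0, seed = 100L + seed
    )
    sim <- simulate_cohort(cfg, gwas_n = 1e3)
    res <- screen_exposures(incident_subset(sim$cohort), paste0("x", 1:6))
    hits <- hits + sum(res$discovery[!duplicated(res$exposure)])
    total <- total + 6
  }
  expect_lte(hits / total, 0.05 + 2 * sqrt(0.05 * 0.95 / total))
})

test_that("matched designs assemble exact 4:1 strata deterministically", {
  base <- tibble::tibble(
    id = sprintf("C%02d", 1:22),
    age = c(60, 65, rep(60, 10), rep(65, 10)),
    sex = "male", ethnicity = "white_british",
    pd_status = c(1, 1, rep(0, 20)),
    incident = c(1, 1, rep(0, 20))
  )
  m <- matched_design(base, ratio = 4, seed = 3L)
  expect_identical(nrow(m), 10L)
  expect_equal(sum(m$pd_status), 2)
  expect_equal(sum(m$pd_status == 0), 8)
  for (mid in unique(m$match_id)) {
    set <- m[m$match_id == mid, ]
    case <- set[set$pd_status == 1, ]
    ctrl <- set[set$pd_status == 0, ]
    expect_true(all(abs(ctrl$age - case$age) <= 1))
    expect_true(all(ctrl$sex == case$sex))
  }
  # same seed, same matched set
  m2 <- matched_design(base, ratio = 4, seed = 3L)
  expect_identical(m, m2)
  # a case with too few eligible controls is dropped with a warning
  short <- base[c(1, 3:5), ] # 1 case, 3 matching controls
  expect_warning(m3 <- matched_design(short, ratio = 4, seed = 1L),
                 "dropped")
  expect_identical(nrow(m3), 0L)
})
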
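---
title: "Methods: polygenic scores, risk prediction and gene-environment interaction for incident Parkinson's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic scores, risk prediction and gene-environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdrisk)
```

# Overview

`pdrisk` implements an analysis pipeline for studying determinants and
prediction of incident Parkinson's disease (PD) in a genotyped cohort:

1. **Synthetic cohort generation** — genotypes in LD blocks, external GWAS
   summary statistics, binary exposures, an incident-disease outcome model,
   kinship pairs and ancestry principal components, all with known
   generative parameters.
2. **Quality control** — variant filters (overlap, duplicates, palindromes,
   MAF, missingness, Hardy-Weinberg, imputation quality), sample filters
   (missingness, ancestry label) and greedy relatedness pruning.
3. **Polygenic risk score (PRS)** construction by clumping and
   thresholding (C+T), with model selection by Nagelkerke's pseudo-R² on a
   training split.
4. **PREDICT-PD**, a published multiplicative risk algorithm combining
   age-based baseline odds with fixed trait multipliers.
5. **Incident case-control association** — adjusted logistic models per
   risk factor, likelihood-ratio tests under Benjamini-Hochberg FDR
   control, a combined multivariable model, and a matched 4:1 sensitivity
   design.
6. **Gene-environment interaction** between the PRS and each exposure on
   the additive scale (RERI and attributable proportion with percentile
   bootstrap CIs) and the multiplicative scale (interaction-term
   likelihood-ratio test).

Every real-data input the analysis would consume (biobank genotypes and
phenotypes, external GWAS summary statistics, a reference LD panel) is
access-restricted in practice, so the synthetic generator is a first-class,
tested component: it defines the study conditions under which every
downstream stage can be validated against known truth.

# The synthetic cohort

## Genotypes and LD

Variants are organised into blocks of `ld_block_size` sites. Each
haplotype is a thresholded first-order autoregressive Gaussian process:
adjacent latent values within a block correlate at `ld_decay` (default
0.8), so allelic correlation decays geometrically with distance and is
zero across block boundaries. Dosage is the sum of two haplotypes, giving
hard calls in {0, 1, 2}. Blocks sit 2 Mb apart (sites 10 kb apart), so a
250 kb clumping window never spans blocks. This is deliberately the
simplest structure that makes clumping non-trivial; it does not attempt
realistic human LD maps, admixture, or X-chromosome inheritance, so
passing tests demonstrate algorithmic correctness, not robustness to real
LD pathologies.

To give the QC stage real work, roughly 5% of variants are made
palindromic (A/T or C/G), 2% receive low imputation quality and 2%
extreme Hardy-Weinberg p-values; causal variants are drawn from the
clean remainder so QC never silently destroys the simulated signal.

## Summary statistics

An external GWAS of `gwas_n` samples is emulated directly on the effect
scale: the estimated per-allele log-odds ratio is the true effect plus
Gaussian noise with variance `1 / (2 * gwas_n * maf * (1 - maf))` — the
standard large-sample variance of a per-allele effect estimate — and the
p-value is the two-sided Wald test. Non-causal variants have true effect
zero, so their p-values are uniform; as `gwas_n` grows the estimates
converge to the truth. Running an actual GWAS regression per variant is
out of scope.

## Disease model

Disease probability follows a logistic model: baseline log-odds (default
−2.5, i.e. about 8% prevalence at the reference profile), age centred at
60 (default +0.05/year), male sex (+0.4), the standardised latent genetic
score (`prs_coefficient`, default log 1.5 per SD), binary exposure
effects, and optional score-by-exposure interaction terms. Using a
logistic rather than liability-threshold model means the downstream
logistic analyses recover the generative coefficients exactly in
expectation, which is what makes the interaction-recovery and
calibration tests sharp.

A fraction of cases (default 0.6) is flagged incident. Cases receive an
age at diagnosis `onset_base − onset_slope × score + noise` (defaults 66
years, 0.5 years/SD, SD 5) — values chosen once as a plausible cohort
onset distribution with a recoverable negative score-onset association;
the sign, not the magnitude, is the tested property. Principal components
are low-variance Gaussians with an ethnicity-linked offset; kinship pairs
are recorded as a metadata table (haplotype sharing between relatives is
not simulated, since relatedness pruning operates on the pair list
alone).

One integer seed governs everything through fixed per-component child
streams, so identical configurations are byte-identical and components
can be regenerated independently.

# Quality control

Thresholds follow standard genotype-array practice: exclude minor allele
frequency < 0.01, per-variant missingness > 10%, Hardy-Weinberg
p < 1e-6, imputation quality < 0.3, per-sample missingness > 10%, and one
member of each pair related at kinship ≥ 0.0442 (third-degree). All
inequalities are strict on the exclusion side, so boundary values
survive. Duplicate rsIDs and positions keep their first occurrence.
Hardy-Weinberg p-values are taken from variant metadata when present and
otherwise computed by the exact conditional test on the analysis
genotypes.

Relatedness pruning removes the highest-degree node of the kinship graph
repeatedly (ties broken lexicographically), which keeps more individuals
than dropping one member of every pair in multi-relative clusters and is
deterministic. Ancestry restriction is a label filter; principal
components are carried as covariates rather than used for ellipsoid
assignment.

# Clumping and thresholding

Candidates are built over a grid of p-value thresholds (default 5e-5 to
1) and clumping r² thresholds (0.1-0.8) with a 250 kb window. Clumping is
greedy: variants sort by ascending p (ties by position, then rsid); the
best unclaimed variant becomes an index and claims all unclaimed variants
on its chromosome within the window whose squared Pearson dosage
correlation on the reference panel (pairwise-complete) reaches the
threshold. The implementation is checked against an exhaustive
transcription of this definition on random instances.

Per-locus scores are effect-allele dosage × beta. Each locus is
standardised by the mean and SD of its per-locus score — the
standardisation constants are estimated on training individuals only and
frozen into the model, preventing test-set leakage. (Standardising the
per-locus *score* rather than the raw dosage is one reading of
"standardised per SNP"; the choice is recorded in the serialised model
file.) Missing dosages and model variants absent from a target dataset
contribute the per-locus mean, i.e. exactly zero after standardisation;
scoring fails only when more than half the model variants are absent.
Dosages counted on the opposite allele are flipped to `2 − dosage`, so
scores are invariant to counted-allele orientation.

Model selection compares, per candidate, logistic models of case status
on age, sex, deprivation and four PCs with and without the score, via
Nagelkerke's pseudo-R² on the training split; the raw maximum wins (no
one-standard-error rule), with ties broken toward fewer SNPs. A
known-loci-excluded score removes variants within 1 Mb (inclusive) of
supplied lead SNPs and re-fits standardisation.

# PREDICT-PD

Baseline odds follow
`odds(age) = 1 / (1 + 28.53049 + 73.67057 · e^{−0.165308 (age − 60)})`,
monotone increasing in age with asymptote 1/29.53049. (The published
typesetting of this equation is ambiguous; this is the only reading that
is positive, increasing in age, and produces probabilities in the range
the algorithm's validation studies report — about 0.3-0.8% at cohort
ages.) Trait multipliers then scale the odds: /1.5 for females, ×0.44
current and ×0.78 previous smoking, ×4.45 family history of PD, ×0.67
coffee, ×0.9 alcohol, ×2.34 constipation, ×1.86 anxiety or depression,
×3.8 erectile dysfunction (males only; the multiplier is skipped, not
imputed, for females). Missing traits count as absent. "Anxiety or
depression" maps to the logical OR of separate anxiety and depression
fields when both exist. Factors commute, so adjusted odds are invariant
to application order.

# Association analysis

Incident analyses use incident cases plus all undiagnosed participants
as unmatched controls; prevalent cases are excluded. (PRS training and
selection, by contrast, use all cases, prevalent and incident.) Each risk
factor is fitted as `status ~ age + sex + ethnicity + deprivation +
factor` by maximum likelihood (tolerance 1e-8, 100 iterations) on
complete cases per model; sex is dropped from covariates for
sex-specific factors. Effects are reported as Wald ORs with 95% CIs, and
model improvement as the likelihood-ratio test against the
covariate-only model. LRT p-values are adjusted by Benjamini-Hochberg
step-up across the exposure family — the conventional implementation of
an "FDR < 0.05" rule; whether a local-FDR variant was intended in the
original analyses is left open, and the procedure is confined to one
function so it can be swapped. Degenerate exposures, aliased
coefficients and separation (detected by non-convergence, fitted
probabilities at the boundary, or |log-OR| > 15) produce flagged rows
rather than silent omissions.

The matched sensitivity design samples, per incident case, exactly four
unused controls of identical sex and ethnicity with age within ±1 year
(exact-year matching empties strata in small cohorts); cases with too few
eligible controls are dropped with a warning, deterministically under a
seed.

# Gene-environment interaction

For two risk factors x and y in
`logit p = β0 + β1 x + β2 y + β12 xy + covariates`:

- `RERI = exp(β1+β2+β12) − exp(β1) − exp(β2) + 1` measures departure
  from additivity of the two odds ratios (zero under the additive null
  even when β12 ≠ 0);
- `AP = RERI / exp(β1+β2+β12)` is the proportion of disease in the
  doubly exposed group attributable to interaction; negative values mean
  a sub-additive joint effect.

Continuous factors (the PRS in particular) are first mapped to normal
quantiles by the rank-based inverse normal transform with the Blom
offset, `Φ⁻¹((rank − 3/8)/(n + 1/4))`, average ranks for ties; RERI/AP
contrasts for continuous factors are per SD of the transformed variable
(the extreme-strata alternative is noted as an open choice). AP
confidence intervals come from resampling individuals with replacement —
the whole dataset, no case-control stratification — refitting, and
taking empirical 2.5/97.5 percentiles over converged replicates (default
5000); replicate failures are counted and results with >10% failures
flagged. Bootstrap refits run on a precomputed model matrix via
`glm.fit`, which is the same IRLS as `glm` without per-replicate formula
overhead. Multiplicative-scale interaction is the likelihood-ratio test
of the interaction term, FDR-adjusted across the exposure family.
Family-history exposures are excluded from the default interaction
family because they overlap the PRS; smoking is collapsed to ever/never.

# Evaluation

The cohort splits 30/70 into training and testing, stratified by case
status (stabilising metrics in small cohorts), deterministic under seed.
Nagelkerke's pseudo-R² is Cox-Snell `1 − exp(2(ll0 − ll1)/n)` rescaled by
its maximum `1 − exp(2·ll0/n)`. AUC is the tie-corrected rank
(Mann-Whitney) statistic. Calibration is reported as the slope and
intercept of a logistic regression of outcomes on predicted log-odds
(slope 1/intercept 0 is perfect); Hosmer-Lemeshow is deliberately
omitted. Model comparison fits PREDICT-PD log-odds + 4 PCs, then adds
the PRS and the known-loci-excluded PRS, reporting each model's metrics
plus the incremental pseudo-R² and LRT over the base model. Generic
bootstrap CIs for metrics use the normal approximation
(estimate ± 1.96 × bootstrap SD, default 1000 replicates).

# Pipeline, sizes and numerical choices

`run_pipeline()` chains `simulate → qc → prs → predictpd → assoc →
interact → evaluate`, writing TSV/JSON intermediates and line-delimited
JSON logs; any stage re-runs from the intermediates on disk. A packaged
configuration (`inst/extdata/config-small.yaml`) runs the full chain on
5000 individuals × 500 variants in about a minute.

The test-suite simulations are sized to the smallest n at which each
property is sharp: parameter-recovery and decile-trend checks use
100,000-200,000 individuals with 100-500 variants; bootstrap coverage
uses 20 replicate cohorts of 5000 with 500 bootstrap draws; oracle
equivalences (clumping, BH, AUC, RERI/AP) use exhaustive or closed-form
comparisons on instances small enough to enumerate. Logistic fits use
`stats::glm`; ties in ranks use average ranks; deciles use `dplyr::ntile`
on the relevant score distribution.

## What the synthetic tests do and do not show

Passing the suite demonstrates that each stage implements its definition
correctly and that generative parameters are recovered under the stated
model. It does not demonstrate robustness to real-data features the
generator omits: realistic LD, genotyping batch effects, imputation
error correlated with frequency, confounded exposures, non-logistic risk,
informative missingness, or ancestry structure beyond a label and a PC
offset.
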
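Package: pdrisk
Title: Polygenic Risk Scores, Risk Prediction and Gene-Environment
    Interaction for Incident Parkinson's Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for studying determinants and prediction of
    incident Parkinson's disease in large cohorts. Provides a synthetic cohort
    generator (genotypes in linkage-disequilibrium blocks, GWAS summary
    statistics, exposures, incident outcomes, kinship and ancestry principal
    components), variant- and sample-level genotype quality control with
    relatedness pruning, clumping-and-thresholding polygenic risk score
    construction with Nagelkerke pseudo-R2 model selection, the PREDICT-PD
    age-and-trait multiplicative risk algorithm, incident case-control
    association modelling with likelihood-ratio tests and false discovery rate
    control, and additive (RERI, attributable proportion) and multiplicative
    gene-environment interaction statistics with percentile bootstrap
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
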
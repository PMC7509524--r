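# Packaged small end-to-end configuration: a 5000-individual, 500-variant
# synthetic cohort sized so the full pipeline completes in minutes on one CPU.
seed: 42
simulate:
  n_individuals: 5000
  n_variants: 500
  n_causal: 20
  ld_block_size: 10
  ld_decay: 0.8
  baseline_log_odds: -2.0
  prs_coefficient: 0.405
  missing_genotype_rate: 0.01
  n_related_pairs: 25
  seed: 42
  gwas_n: 100000
train_fraction: 0.30
n_boot_select: 0
n_boot_ap: 200
assoc_q_level: 0.05
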
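#' Serialise / read a polygenic score model
#'
#' The model is written as a TSV of per-variant records (`SNP`, `CHR`, `BP`,
#' `A1`, `A2`, `BETA`, `MEAN`, `SD` — the standardisation constants are of
#' the per-locus score, dosage times beta) plus a JSON sidecar carrying the
#' grid parameters.
#'
#' @param model A fitted `pd_prs_model`.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return Invisibly, the TSV path.
#' @export
write_prs_model <- function(model, prefix) {
  stopifnot(inherits(model, "pd_prs_model"))
  v <- model$variants
  write_tsv_plain(
    data.frame(SNP = v$rsid, CHR = v$chrom, BP = v$pos, A1 = v$a1,
               A2 = v$a2, BETA = v$beta, MEAN = v$mean, SD = v$sd),
    paste0(prefix, ".tsv")
  )
  jsonlite::write_json(
    list(p_threshold = model$p_threshold, r2_threshold = model$r2_threshold,
         n_snps = model$n_snps, standardisation = "per-locus score (dosage x beta)"),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(paste0(prefix, ".tsv"))
}

#' @rdname write_prs_model
#' @export
read_prs_model <- function(prefix) {
  tab <- read_tsv_plain(paste0(prefix, ".tsv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  v <- tibble::tibble(rsid = tab$SNP, chrom = as.character(tab$CHR),
                      pos = as.integer(tab$BP), a1 = tab$A1, a2 = tab$A2,
                      beta = tab$BETA, mean = tab$MEAN, sd = tab$SD)
  new_prs_model(v, meta$p_threshold, meta$r2_threshold)
}

#' Pipeline configuration
#'
#' Reads (or validates) the YAML/list configuration driving
#' [run_pipeline()]. Unspecified entries fall back to package defaults.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated list of class `pd_pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  sim_args <- config$simulate %||% list()
  ints <- sim_args$interaction_specs
  if (!is.null(ints)) sim_args$interaction_specs <- as_spec_tibble(ints)
  exps <- sim_args$exposure_specs
  if (!is.null(exps)) sim_args$exposure_specs <- as_spec_tibble(exps)
  gwas_n <- sim_args$gwas_n %||% 5e4
  sim_args$gwas_n <- NULL
  cfg <- list(
    sim = do.call(sim_config, sim_args),
    gwas_n = gwas_n,
    qc = do.call(qc_thresholds, config$qc %||% list()),
    grid = do.call(ct_grid, config$grid %||% list()),
    train_fraction = config$train_fraction %||% 0.30,
    n_boot_select = config$n_boot_select %||% 0,
    n_boot_ap = config$n_boot_ap %||% 5000,
    assoc_q_level = config$assoc_q_level %||% 0.05,
    gxe_exposures = config$gxe_exposures %||% NULL,
    multipliers = do.call(multiplier_table,
                          as.list(config$predictpd_multipliers %||% list())),
    seed = config$seed %||% 42L
  )
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  class(cfg) <- "pd_pipeline_config"
  cfg
}

as_spec_tibble <- function(x) {
  if (is.data.frame(x)) return(tibble::as_tibble(x))
  dplyr::bind_rows(lapply(x, tibble::as_tibble))
}

log_stage <- function(dir, stage, t0, ...) {
  entry <- c(list(stage = stage,
                  elapsed_s = round(as.numeric(Sys.time()) - t0, 3)),
             list(...))
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = file.path(dir, "pipeline_log.jsonl"),
      append = TRUE)
}

#' Run the analysis pipeline
#'
#' Chains the stages `simulate`, `qc`, `prs`, `predictpd`, `assoc`,
#' `interact` and `evaluate` (or any subset; `"all"` runs everything).
#' Each stage writes its tabular outputs under `dir` and appends a
#' line-delimited JSON log entry (stage, key counts, wall time). A stage
#' run on its own reloads the intermediates written by earlier stages and
#' errors naming the missing stage when they are absent.
#'
#' @param config A [pipeline_config()], YAML path, or list.
#' @param dir Output directory.
#' @param stages Character vector of stage names, or `"all"`.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), dir = tempfile("pdrisk_"),
                         stages = "all") {
  if (!inherits(config, "pd_pipeline_config")) config <- pipeline_config(config)
  all_stages <- c("simulate", "qc", "prs", "predictpd", "assoc", "interact",
                  "evaluate")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  state <- new.env(parent = emptyenv())

  need_sim <- function() {
    if (!exists("sim", state)) {
      cdir <- file.path(dir, "cohort")
      if (!file.exists(file.path(cdir, "manifest.json"))) {
        stop("missing intermediates: run stage 'simulate' first", call. = FALSE)
      }
      state$sim <- read_cohort(cdir)
    }
    state$sim
  }
  need_qc <- function() {
    if (!exists("qc", state)) {
      path <- file.path(dir, "qc_retained.json")
      if (!file.exists(path)) {
        stop("missing intermediates: run stage 'qc' first", call. = FALSE)
      }
      kept <- jsonlite::read_json(path, simplifyVector = TRUE)
      sim <- need_sim()
      g <- sim$genotypes
      vi <- match(kept$variants, g$variants$rsid)
      si <- match(kept$samples, g$sample_ids)
      state$qc <- list(genotypes = new_pd_genotypes(
        g$dosages[si, vi, drop = FALSE], g$variants[vi, , drop = FALSE],
        g$sample_ids[si], g$effects))
    }
    state$qc
  }
  need_scores <- function() {
    if (!exists("scores", state)) {
      path <- file.path(dir, "scores.tsv")
      if (!file.exists(path)) {
        stop("missing intermediates: run stage 'prs' first", call. = FALSE)
      }
      tab <- read_tsv_plain(path)
      state$scores <- tibble::tibble(id = as.character(tab$ID),
                                     score = tab$SCORE,
                                     score_int = tab$SCORE_INT,
                                     score_excl = tab$SCORE_EXCL,
                                     decile = tab$DECILE)
      state$split <- list(
        train_ids = as.character(tab$ID[tab$SPLIT == "train"]),
        test_ids = as.character(tab$ID[tab$SPLIT == "test"])
      )
    }
    list(scores = state$scores, split = state$split)
  }
  need_predictpd <- function() {
    if (!exists("ppd", state)) {
      path <- file.path(dir, "predictpd.tsv")
      if (!file.exists(path)) {
        stop("missing intermediates: run stage 'predictpd' first", call. = FALSE)
      }
      tab <- read_tsv_plain(path)
      state$ppd <- tibble::tibble(id = as.character(tab$ID), odds = tab$ODDS,
                                  prob = tab$PROB, log_odds = tab$LOG_ODDS)
    }
    state$ppd
  }

  for (stage in all_stages[all_stages %in% stages]) {
    t0 <- as.numeric(Sys.time())
    switch(stage,
      simulate = {
        state$sim <- simulate_cohort(config$sim, gwas_n = config$gwas_n)
        write_cohort(state$sim, file.path(dir, "cohort"))
        log_stage(dir, "simulate", t0,
                  n_individuals = config$sim$n_individuals,
                  n_variants = config$sim$n_variants,
                  n_cases = sum(state$sim$cohort$pd_status),
                  seed = config$sim$seed)
      },
      qc = {
        sim <- need_sim()
        fv <- filter_variants(sim$genotypes, sim$sumstats, config$qc)
        fs <- filter_samples(fv$genotypes, sim$cohort, config$qc)
        kin <- sim$kinship[sim$kinship$id1 %in% fs$sample_ids &
                             sim$kinship$id2 %in% fs$sample_ids, ,
                           drop = FALSE]
        unrelated <- prune_related(fs$sample_ids, kin,
                                   config$qc$kinship_cutoff)
        g <- fs$genotypes
        si <- match(unrelated, g$sample_ids)
        state$qc <- list(
          genotypes = new_pd_genotypes(g$dosages[si, , drop = FALSE],
                                       g$variants, unrelated, g$effects),
          variant_report = fv$report, sample_report = fs$report
        )
        jsonlite::write_json(
          list(variants = state$qc$genotypes$variants$rsid,
               samples = state$qc$genotypes$sample_ids),
          file.path(dir, "qc_retained.json")
        )
        jsonlite::write_json(
          list(variant_steps = as.data.frame(fv$report),
               sample_steps = as.data.frame(fs$report),
               n_removed_related = length(fs$sample_ids) - length(unrelated)),
          file.path(dir, "qc_report.json"), auto_unbox = TRUE, digits = NA,
          pretty = TRUE
        )
        log_stage(dir, "qc", t0,
                  variants_retained = nrow(state$qc$genotypes$variants),
                  samples_retained = length(unrelated))
      },
      prs = {
        sim <- need_sim()
        qc <- need_qc()
        g <- qc$genotypes
        cohort <- sim$cohort[sim$cohort$id %in% g$sample_ids, , drop = FALSE]
        sp <- split_cohort(cohort, config$train_fraction, seed = config$seed)
        ti <- match(sp$train_ids, g$sample_ids)
        g_train <- new_pd_genotypes(g$dosages[ti, , drop = FALSE],
                                    g$variants, sp$train_ids, g$effects)
        stats_qc <- sim$sumstats[sim$sumstats$rsid %in% g$variants$rsid, ,
                                 drop = FALSE]
        cands <- build_candidates(stats_qc, g, config$grid,
                                  train_genotypes = g_train)
        sel <- select_best(cands, g_train,
                           cohort[cohort$id %in% sp$train_ids, , drop = FALSE],
                           n_boot = config$n_boot_select, seed = config$seed)
        # known-loci analogue: lead SNPs at the true causal positions
        leads <- if (!is.null(g$effects) && nrow(g$effects)) {
          sim_v <- sim$genotypes$variants
          sim_v[match(g$effects$rsid, sim_v$rsid), c("chrom", "pos")]
        } else tibble::tibble(chrom = character(), pos = integer())
        model_excl <- exclude_known_loci(sel$best, leads, g_train)
        scores <- prs_score(g, sel$best)
        scores$score_excl <- if (model_excl$n_snps > 0) {
          prs_score(g, model_excl)$score
        } else 0
        scores$split <- ifelse(scores$id %in% sp$train_ids, "train", "test")
        state$scores <- scores
        state$split <- sp
        state$selection <- sel
        state$model_excl <- model_excl
        write_prs_model(sel$best, file.path(dir, "prs_model"))
        write_prs_model(model_excl, file.path(dir, "prs_model_excluded"))
        write_tsv_plain(as.data.frame(sel$table),
                        file.path(dir, "prs_selection.tsv"))
        write_tsv_plain(
          data.frame(ID = scores$id, SCORE = scores$score,
                     SCORE_INT = scores$score_int,
                     SCORE_EXCL = scores$score_excl,
                     DECILE = scores$decile, SPLIT = scores$split),
          file.path(dir, "scores.tsv")
        )
        log_stage(dir, "prs", t0, n_candidates = length(cands),
                  best_p_threshold = sel$best$p_threshold,
                  best_r2_threshold = sel$best$r2_threshold,
                  best_n_snps = sel$best$n_snps,
                  best_r2_nagelkerke = sel$table$r2_nagelkerke[sel$best_index])
      },
      predictpd = {
        sim <- need_sim()
        cohort <- dplyr::mutate(
          sim$cohort,
          smoking = ifelse(.data$ever_smoker == 1, "previous", "never"),
          family_history_pd = .data$family_history == 1,
          alcohol_gt1wk = .data$low_alcohol == 0,
          anxiety_or_depression = .data$depression == 1
        )
        state$ppd <- predictpd_risk(cohort, table = config$multipliers)
        write_tsv_plain(
          data.frame(ID = state$ppd$id, ODDS = state$ppd$odds,
                     PROB = state$ppd$prob, LOG_ODDS = state$ppd$log_odds),
          file.path(dir, "predictpd.tsv")
        )
        log_stage(dir, "predictpd", t0, n_scored = nrow(state$ppd),
                  median_prob = stats::median(state$ppd$prob))
      },
      assoc = {
        sim <- need_sim()
        inc <- incident_subset(sim$cohort)
        exposures <- config$sim$exposure_specs$name
        res <- screen_exposures(inc, exposures,
                                q_level = config$assoc_q_level)
        hits <- unique(res$exposure[res$discovery & !res$flagged])
        combined <- if (length(hits)) fit_combined_model(inc, hits) else NULL
        state$assoc <- list(screen = res, combined = combined)
        write_tsv_plain(as.data.frame(res), file.path(dir, "assoc.tsv"))
        if (!is.null(combined)) {
          write_tsv_plain(as.data.frame(combined),
                          file.path(dir, "assoc_combined.tsv"))
        }
        log_stage(dir, "assoc", t0, n_exposures = length(exposures),
                  n_discoveries = length(hits),
                  n_incident_cases = sum(inc$pd_status))
      },
      interact = {
        sim <- need_sim()
        sc <- need_scores()
        test <- dplyr::inner_join(
          sim$cohort[sim$cohort$id %in% sc$split$test_ids, , drop = FALSE],
          sc$scores[, c("id", "score_int")], by = "id"
        )
        test <- incident_subset(test)
        exposures <- config$gxe_exposures %||%
          setdiff(config$sim$exposure_specs$name, "family_history")
        state$gxe <- gxe_scan(test, exposures, score_col = "score_int",
                              n_boot = config$n_boot_ap, seed = config$seed)
        write_tsv_plain(as.data.frame(state$gxe), file.path(dir, "gxe.tsv"))
        log_stage(dir, "interact", t0, n_exposures = length(exposures),
                  n_boot = config$n_boot_ap)
      },
      evaluate = {
        sim <- need_sim()
        sc <- need_scores()
        ppd <- need_predictpd()
        test <- sim$cohort[sim$cohort$id %in% sc$split$test_ids, , drop = FALSE]
        test <- dplyr::inner_join(test, sc$scores[, c("id", "score",
                                                      "score_int",
                                                      "score_excl")],
                                  by = "id")
        test <- dplyr::inner_join(test, ppd[, c("id", "log_odds")], by = "id")
        inc_test <- incident_subset(test)
        cmp <- compare_models(inc_test, "log_odds", "score_int",
                              prs_excluded = "score_excl")
        dec <- decile_analysis(inc_test[, c("id", "score")], inc_test)
        onset <- tryCatch(
          onset_model(test[, c("id", "score_int")], test),
          error = function(e) NULL
        )
        state$evaluation <- list(comparison = cmp, deciles = dec,
                                 onset = onset)
        write_tsv_plain(as.data.frame(cmp),
                        file.path(dir, "model_comparison.tsv"))
        write_tsv_plain(as.data.frame(dec), file.path(dir, "deciles.tsv"))
        eval_json <- list(
          comparison = as.data.frame(cmp),
          onset = if (!is.null(onset)) {
            list(slope = onset$slope, se = onset$se, p = onset$p,
                 n = onset$n)
          } else NULL
        )
        jsonlite::write_json(eval_json, file.path(dir, "evaluate.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        log_stage(dir, "evaluate", t0,
                  n_test = nrow(test),
                  top_decile_or = dec$or[dec$decile == 10])
      }
    )
  }
  invisible(as.list(state))
}
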
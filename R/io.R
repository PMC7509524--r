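#' Write a synthetic cohort to disk
#'
#' Emits the full cohort as plain-text, round-trippable files: genotypes as
#' VCF 4.2 (GT field, missing calls as `./.`; per-variant allele frequency,
#' imputation quality and Hardy-Weinberg p carried as INFO keys), summary
#' statistics / phenotypes / kinship / true effects as tab-separated tables,
#' and a JSON manifest recording the generating configuration and seed.
#'
#' @param sim A `pd_cohort_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written file paths.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "pd_cohort_sim"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir, call. = FALSE)
  }
  paths <- c(
    genotypes = file.path(dir, "genotypes.vcf"),
    sumstats = file.path(dir, "sumstats.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    kinship = file.path(dir, "kinship.tsv"),
    effects = file.path(dir, "true_effects.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_vcf(sim$genotypes, paths[["genotypes"]])
  ss <- sim$sumstats
  write_tsv_plain(
    data.frame(SNP = ss$rsid, CHR = ss$chrom, BP = ss$pos, A1 = ss$a1,
               A2 = ss$a2, BETA = ss$beta, SE = ss$se, P = ss$p,
               FREQ = ss$freq),
    paths[["sumstats"]]
  )
  write_tsv_plain(as.data.frame(sim$cohort), paths[["phenotypes"]])
  kin <- sim$kinship
  write_tsv_plain(
    data.frame(ID1 = kin$id1, ID2 = kin$id2, KINSHIP = kin$kinship),
    paths[["kinship"]]
  )
  eff <- sim$genotypes$effects %||% tibble::tibble(rsid = character(),
                                                   beta = numeric())
  write_tsv_plain(as.data.frame(eff), paths[["effects"]])
  manifest <- list(
    package = "pdrisk",
    seed = sim$config$seed,
    config = config_to_list(sim$config)
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$exposure_specs <- as.data.frame(out$exposure_specs)
  out$interaction_specs <- as.data.frame(out$interaction_specs)
  out
}

write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
}

#' Write genotypes as VCF 4.2
#'
#' The effect allele (`a1`) is written as ALT so that the stored dosage is
#' the ALT allele count; missing dosages become `./.`; `maf`, `info` and
#' `hwe_p` are preserved as the INFO keys `AF`, `R2` and `HWE`.
#'
#' @param genotypes A `pd_genotypes`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "pd_genotypes"))
  v <- genotypes$variants
  D <- genotypes$dosages
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pdrisk",
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Effect allele frequency">',
    '##INFO=<ID=R2,Number=1,Type=Float,Description="Imputation quality">',
    '##INFO=<ID=HWE,Number=1,Type=Float,Description="Hardy-Weinberg p-value">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0("##contig=<ID=", unique(v$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$sample_ids), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    d <- D[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    info <- sprintf("AF=%.6g;R2=%.6g;HWE=%.6g", v$maf[j], v$info[j], v$hwe_p[j])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$rsid[j], v$a2[j], v$a1[j],
                       ".", "PASS", info, "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF written by [write_vcf()] (or any biallelic VCF with GT
#' calls) into a `pd_genotypes`; dosage is the ALT allele count, ALT is
#' taken as the effect allele.
#'
#' @param path VCF file path.
#' @return A `pd_genotypes`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required to read VCF files", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  alt_count <- function(s) {
    out <- rep(NA_integer_, length(s))
    ok <- !is.na(s) & !(s %in% c("./.", ".|."))
    out[ok] <- vapply(strsplit(s[ok], "[/|]"),
                      function(a) sum(a == "1"), 1L)
    out
  }
  info_field <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    as.numeric(sub(paste0(".*", key, "="), "", m))
  }
  variants <- tibble::tibble(
    rsid = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    a1 = fix$ALT,
    a2 = fix$REF,
    maf = info_field(fix$INFO, "AF"),
    info = info_field(fix$INFO, "R2"),
    hwe_p = info_field(fix$INFO, "HWE")
  )
  sample_ids <- colnames(gt)
  D <- matrix(NA_integer_, length(sample_ids), nrow(variants),
              dimnames = list(sample_ids, variants$rsid))
  for (j in seq_len(nrow(variants))) {
    D[, j] <- alt_count(gt[j, ])
  }
  new_pd_genotypes(D, variants, sample_ids)
}

#' Read a synthetic cohort written by [write_cohort()]
#'
#' @param dir Directory holding the cohort files.
#' @return A list of class `pd_cohort_sim` with elements `genotypes`,
#'   `sumstats`, `cohort`, `kinship` and `manifest` (the parsed JSON
#'   manifest; the full `config` object is not reconstructed).
#' @export
read_cohort <- function(dir) {
  genotypes <- read_genotypes_vcf(file.path(dir, "genotypes.vcf"))
  ss <- read_tsv_plain(file.path(dir, "sumstats.tsv"))
  sumstats <- tibble::tibble(
    rsid = ss$SNP, chrom = as.character(ss$CHR), pos = as.integer(ss$BP),
    a1 = ss$A1, a2 = ss$A2, beta = ss$BETA, se = ss$SE, p = ss$P,
    freq = ss$FREQ
  )
  cohort <- tibble::as_tibble(read_tsv_plain(file.path(dir, "phenotypes.tsv")))
  kin <- read_tsv_plain(file.path(dir, "kinship.tsv"))
  kinship <- tibble::tibble(id1 = as.character(kin$ID1),
                            id2 = as.character(kin$ID2),
                            kinship = kin$KINSHIP)
  eff_path <- file.path(dir, "true_effects.tsv")
  if (file.exists(eff_path)) {
    eff <- read_tsv_plain(eff_path)
    if (nrow(eff)) genotypes$effects <- tibble::as_tibble(eff)
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(
    list(genotypes = genotypes, sumstats = sumstats, cohort = cohort,
         kinship = kinship, manifest = manifest),
    class = "pd_cohort_sim"
  )
}

read_tsv_plain <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             colClasses = NA, check.names = FALSE)
}
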
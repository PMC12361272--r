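format_ds <- function(x) ifelse(is.na(x), ".", formatC(x, format = "g", digits = 15))

#' Write a genotype dosage matrix as VCF 4.2
#'
#' One record per variant, genotypes carried in a `DS` (expected allele
#' dosage) FORMAT field; missing dosages are written as `.`.
#'
#' @param geno A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(geno, path) {
  v <- geno$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=grskit",
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Expected allele count dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno$dosage)), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chr[i], v$pos[i], v$id[i], v$a2[i], v$a1[i], ".", "PASS", ".",
            "DS", format_ds(geno$dosage[, i])), collapse = "\t")
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a dosage VCF into a genotype matrix
#'
#' Reads a VCF with a `DS` FORMAT field (as written by
#' [write_dosage_vcf()]); `.` entries become missing. The ALT allele is
#' taken as the counted (effect) allele `a1`.
#'
#' @param path VCF file path.
#' @return A [geno_matrix()].
#' @export
read_dosage_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = FALSE)
  if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(fix), dimnames = list(NULL, names(ds)))
  ds[ds == "."] <- NA_character_
  # extract.gt returns variants x samples; transpose to individuals x variants
  dosage <- t(matrix(suppressWarnings(as.numeric(ds)),
                     nrow = nrow(ds), ncol = ncol(ds)))
  dimnames(dosage) <- list(colnames(ds), unname(fix[, "ID"]))
  variants <- data.frame(id = unname(fix[, "ID"]), chr = unname(fix[, "CHROM"]),
                         pos = as.integer(fix[, "POS"]),
                         a1 = unname(fix[, "ALT"]), a2 = unname(fix[, "REF"]),
                         stringsAsFactors = FALSE)
  geno_matrix(dosage, variants)
}

#' Write a simulated cohort to a directory
#'
#' Emits `genotypes.vcf` (DS dosage field), `phenotype.tsv`
#' (`iid status sex PC1..`), `hla.tsv` (unphased four-digit typing),
#' `phased.tsv` and `tag_alleles.tsv` when phased truth is present, and
#' `truth.json` (the generating config and realized frequencies). The
#' files round-trip losslessly through [read_cohort()].
#'
#' @param cohort A [simulate_cohort()] cohort.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    stop_if_not(ok, "cannot create output directory %s", dir)
  }
  if (!is.null(cohort$genotypes))
    write_dosage_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  covs <- cohort$covariates
  for (j in seq_along(covs)) if (is.double(covs[[j]]))
    covs[[j]] <- sprintf("%.17g", covs[[j]]) # lossless float round-trip
  pheno <- data.frame(iid = rownames(cohort$covariates),
                      status = cohort$phenotype, covs,
                      stringsAsFactors = FALSE)
  utils::write.table(pheno, file.path(dir, "phenotype.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$hla))
    utils::write.table(cohort$hla, file.path(dir, "hla.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$phased)) {
    ph <- data.frame(iid = rownames(cohort$phased), hap1 = cohort$phased[, 1],
                     hap2 = cohort$phased[, 2], stringsAsFactors = FALSE)
    utils::write.table(ph, file.path(dir, "phased.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cohort$tag_alleles))
    utils::write.table(cohort$tag_alleles, file.path(dir, "tag_alleles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$truth$config
  truth <- list(
    config = list(
      n_cases = cfg$n_cases, n_controls = cfg$n_controls,
      haplotype_pool = cfg$haplotype_pool,
      interaction_effects = as.list(cfg$interaction_effects),
      tag_specs = as.list(cfg$tag_specs),
      nonhla_snps = cfg$nonhla_snps,
      sex_beta = cfg$sex_beta, pc_betas = cfg$pc_betas,
      intercept = cfg$intercept, missing_rate = cfg$missing_rate,
      seed = cfg$seed),
    hap_freq = as.list(cohort$truth$hap_freq),
    snp_freq = as.list(cohort$truth$snp_freq),
    n_draws = cohort$truth$n_draws,
    raw_case_rate = cohort$truth$raw_case_rate,
    acceptance_rate = cohort$truth$acceptance_rate,
    tag_map = as.list(cohort$tag_map))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory path.
#' @return A `cohort` object.
#' @export
read_cohort <- function(dir) {
  stop_if_not(dir.exists(dir), "no such cohort directory: %s", dir)
  genotypes <- NULL
  if (file.exists(file.path(dir, "genotypes.vcf")))
    genotypes <- read_dosage_vcf(file.path(dir, "genotypes.vcf"))
  pheno <- utils::read.table(file.path(dir, "phenotype.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  covariates <- pheno[, setdiff(names(pheno), c("iid", "status")), drop = FALSE]
  rownames(covariates) <- pheno$iid
  hla <- NULL
  if (file.exists(file.path(dir, "hla.tsv")))
    hla <- utils::read.table(file.path(dir, "hla.tsv"), sep = "\t",
                             header = TRUE, colClasses = "character")
  phased <- NULL
  if (file.exists(file.path(dir, "phased.tsv"))) {
    ph <- utils::read.table(file.path(dir, "phased.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
    phased <- cbind(hap1 = ph$hap1, hap2 = ph$hap2)
    rownames(phased) <- ph$iid
  }
  tag_alleles <- NULL
  if (file.exists(file.path(dir, "tag_alleles.tsv"))) {
    tag_alleles <- as.matrix(utils::read.table(
      file.path(dir, "tag_alleles.tsv"), sep = "\t", header = TRUE,
      check.names = FALSE))
    storage.mode(tag_alleles) <- "integer"
  }
  truth <- NULL; tag_map <- NULL
  if (file.exists(file.path(dir, "truth.json"))) {
    tj <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
    cfgl <- tj$config
    cfg <- sim_config(
      n_cases = cfgl$n_cases, n_controls = cfgl$n_controls,
      haplotype_pool = cfgl$haplotype_pool,
      interaction_effects = if (length(cfgl$interaction_effects))
        unlist(cfgl$interaction_effects) else NULL,
      tag_specs = if (length(cfgl$tag_specs)) unlist(cfgl$tag_specs) else NULL,
      nonhla_snps = cfgl$nonhla_snps,
      sex_beta = cfgl$sex_beta, pc_betas = cfgl$pc_betas,
      intercept = cfgl$intercept, missing_rate = cfgl$missing_rate,
      seed = cfgl$seed)
    truth <- list(config = cfg,
                  hap_freq = if (length(tj$hap_freq)) unlist(tj$hap_freq) else NULL,
                  snp_freq = if (length(tj$snp_freq)) unlist(tj$snp_freq) else NULL,
                  n_draws = tj$n_draws, raw_case_rate = tj$raw_case_rate,
                  acceptance_rate = tj$acceptance_rate)
    if (length(tj$tag_map)) tag_map <- unlist(tj$tag_map)
  }
  cohort <- list(genotypes = genotypes, phased = phased, hla = hla,
                 phenotype = as.integer(pheno$status), covariates = covariates,
                 truth = truth, tag_alleles = tag_alleles, tag_map = tag_map)
  class(cohort) <- "cohort"
  cohort
}
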
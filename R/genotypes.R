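#' Construct a genotype dosage matrix
#'
#' The package substrate for QC, association and scoring: an individuals x
#' variants matrix of expected effect-allele counts (dosages) in [0, 2],
#' with `NA` marking missing calls, plus a variant annotation table. The
#' effect (counted) allele is `a1`.
#'
#' @param dosage Numeric matrix, individuals in rows (rownames = sample ids),
#'   variants in columns (colnames = variant ids).
#' @param variants data.frame with columns `id`, `chr`, `pos`, `a1`, `a2`,
#'   aligned to the columns of `dosage`.
#' @return Object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, variants) {
  stop_if_not(is.matrix(dosage), "dosage must be a matrix")
  stop_if_not(nrow(variants) == ncol(dosage),
              "variants table (%d rows) does not match dosage columns (%d)",
              nrow(variants), ncol(dosage))
  stop_if_not(identical(as.character(variants$id), colnames(dosage)),
              "variant ids must equal dosage column names, in order")
  rng <- range(dosage, na.rm = TRUE)
  stop_if_not(rng[1] >= 0 && rng[2] <= 2, "dosages must lie in [0, 2]")
  structure(list(dosage = dosage, variants = variants), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d variants, %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage), 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

# bind extra columns (e.g. tag SNPs) onto a geno_matrix
append_variants <- function(geno, dosage, variants) {
  geno_matrix(cbind(geno$dosage, dosage), rbind(geno$variants, variants))
}

# "DQA1*03:02-DQB1*03:03" -> c(dqa1 = "03:02", dqb1 = "03:03")
split_hap_label <- function(label) {
  m <- regmatches(label, regexec("^DQA1\\*([0-9:]+)-DQB1\\*([0-9:]+)$", label))
  bad <- vapply(m, length, 1L) != 3L
  stop_if_not(!any(bad), "malformed haplotype label(s): %s",
              paste(label[bad], collapse = ", "))
  cbind(dqa1 = vapply(m, `[`, "", 2L), dqb1 = vapply(m, `[`, "", 3L))
}

make_hap_label <- function(dqa1, dqb1) {
  sprintf("DQA1*%s-DQB1*%s", dqa1, dqb1)
}
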
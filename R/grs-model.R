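GRS_SCHEMA_VERSION <- "1.0"

#' Assemble an interaction-aware genetic risk score model
#'
#' Weights are per-allele natural logs of odds ratios: `beta = ln(OR)` for
#' every retained term. DQ haplotype additive weights are taken from the
#' haplotype association table; haplogenotype lookup scores come from the
#' interaction table; HLA terms outside DQ are retained at
#' `p < 4.72e-4` (Bonferroni over the 106 tested alleles) and non-HLA SNPs
#' at genome-wide `p < 5e-8` (both configurable). Rows with OR <= 0 are
#' rejected.
#'
#' @param dq_assoc Optional data.frame (`label`, and `or` or `beta`;
#'   optional `p`) of DQ haplotype additive effects (pre-filtered by the
#'   frequency rule).
#' @param interaction_table Optional [significant_interactions()] table.
#' @param hla_other_assoc Optional [run_gwas()]-style table for HLA SNPs
#'   outside DQ.
#' @param non_hla_assoc Optional [run_gwas()]-style table for non-HLA SNPs.
#' @param hla_p,nonhla_p Retention thresholds.
#' @param metadata Optional list stored verbatim (cohort, date, ...).
#' @return Object of class `grs_model` with elements `dq_additive`,
#'   `dq_interactions`, `hla_other`, `non_hla` (named numeric vectors),
#'   `effect_alleles`, `metadata`, `version`.
#' @export
build_model <- function(dq_assoc = NULL, interaction_table = NULL,
                        hla_other_assoc = NULL, non_hla_assoc = NULL,
                        hla_p = 4.72e-4, nonhla_p = 5e-8, metadata = list()) {
  get_beta <- function(tab, what) {
    if (is.null(tab) || !nrow(tab)) return(numeric(0))
    b <- if ("beta" %in% names(tab) && !all(is.na(tab$beta))) tab$beta
         else {
           stop_if_not(all(tab$or > 0, na.rm = TRUE), "%s: OR <= 0 in input row", what)
           log(tab$or)
         }
    stop_if_not(all(is.finite(b)), "%s: non-finite weight", what)
    b
  }
  dq_additive <- numeric(0)
  if (!is.null(dq_assoc) && nrow(dq_assoc))
    dq_additive <- stats::setNames(get_beta(dq_assoc, "dq_assoc"), dq_assoc$label)

  dq_interactions <- numeric(0)
  if (!is.null(interaction_table) && nrow(interaction_table))
    dq_interactions <- stats::setNames(interaction_table$score, interaction_table$key)

  take_snps <- function(tab, thr, what) {
    if (is.null(tab) || !nrow(tab)) return(list(beta = numeric(0), ea = character(0)))
    keep <- !is.na(tab$p) & tab$p < thr
    tab <- tab[keep, , drop = FALSE]
    # provenance: rank of each SNP by association p-value
    tab <- tab[order(tab$p), , drop = FALSE]
    list(beta = stats::setNames(get_beta(tab, what), tab$id),
         ea = stats::setNames(if ("a1" %in% names(tab)) tab$a1
                              else rep(NA_character_, nrow(tab)), tab$id))
  }
  ho <- take_snps(hla_other_assoc, hla_p, "hla_other")
  nh <- take_snps(non_hla_assoc, nonhla_p, "non_hla")

  model <- list(dq_additive = dq_additive, dq_interactions = dq_interactions,
                hla_other = ho$beta, non_hla = nh$beta,
                effect_alleles = c(ho$ea, nh$ea),
                metadata = c(metadata, list(built = format(Sys.time(), "%Y-%m-%d"))),
                version = GRS_SCHEMA_VERSION)
  class(model) <- "grs_model"
  model
}

#' @export
print.grs_model <- function(x, ...) {
  cat(sprintf(paste0("grskit GRS model (schema %s): %d DQ haplotype weights, ",
                     "%d haplogenotype lookups, %d other-HLA SNPs, %d non-HLA SNPs\n"),
              x$version, length(x$dq_additive), length(x$dq_interactions),
              length(x$hla_other), length(x$non_hla)))
  invisible(x)
}

#' Score one individual under a GRS model
#'
#' The DQ component follows two exclusive paths: if the individual's
#' canonical haplogenotype has a lookup score, that score is used
#' (`dq_path = "interaction_lookup"`); otherwise the additive sum of the
#' two haplotype weights applies (`dq_path = "additive"`). The other-HLA
#' and non-HLA components are `sum(beta * dose)` over the model's SNPs;
#' a model SNP missing from `dosages` scores as dose 0 and is counted.
#' The total is the exact sum of the three components.
#'
#' @param model A [build_model()] object.
#' @param hap_pair Character length-2 haplotype labels, or NULL/NA if
#'   unresolved (DQ component then missing and flagged).
#' @param dosages Named dosage vector covering (a subset of) the model
#'   SNPs.
#' @return One-row data.frame `total dq hla_other non_hla dq_path flagged
#'   n_missing_snps`.
#' @export
score_individual <- function(model, hap_pair = NULL, dosages = NULL) {
  sum_comp <- function(w) {
    if (!length(w)) return(list(v = 0, miss = 0L))
    d <- if (is.null(dosages)) rep(NA_real_, length(w)) else unname(dosages[names(w)])
    miss <- sum(is.na(d))
    d[is.na(d)] <- 0
    list(v = sum(w * d), miss = miss)
  }
  ho <- sum_comp(model$hla_other)
  nh <- sum_comp(model$non_hla)
  dq <- 0; path <- "additive"; flagged <- FALSE
  if (length(model$dq_additive) || length(model$dq_interactions)) {
    if (is.null(hap_pair) || any(is.na(hap_pair))) {
      dq <- NA_real_; path <- "unresolved"; flagged <- TRUE
    } else {
      key <- pair_key(hap_pair[1], hap_pair[2])
      if (key %in% names(model$dq_interactions)) {
        dq <- unname(model$dq_interactions[key])
        path <- "interaction_lookup"
      } else {
        w <- model$dq_additive[hap_pair]
        dq <- sum(ifelse(is.na(w), 0, w))
      }
    }
  }
  data.frame(total = dq + ho$v + nh$v, dq = dq, hla_other = ho$v,
             non_hla = nh$v, dq_path = path, flagged = flagged,
             n_missing_snps = ho$miss + nh$miss, stringsAsFactors = FALSE)
}

#' Score every individual of a cohort
#'
#' Vectorised application of [score_individual()] with a per-cohort
#' summary (median, IQR, tertile bounds) and a missing-SNP report.
#'
#' @param model A [build_model()] object.
#' @param cohort A `cohort` object, or NULL if `hap_pairs`/`dosages` are
#'   given directly.
#' @param hap_pairs n x 2 character matrix of haplotype labels (rows may
#'   be NA for unresolved individuals).
#' @param dosages n x m dosage matrix with SNP-id column names.
#' @return data.frame of class `score_result`: `iid total dq hla_other
#'   non_hla dq_path flagged n_missing_snps`, with attribute `summary`.
#' @export
score_cohort <- function(model, cohort = NULL, hap_pairs = NULL, dosages = NULL) {
  if (!is.null(cohort)) {
    if (is.null(hap_pairs)) hap_pairs <- cohort$phased
    if (is.null(dosages) && !is.null(cohort$genotypes)) dosages <- cohort$genotypes$dosage
  }
  n <- if (!is.null(dosages)) nrow(dosages) else nrow(hap_pairs)
  iids <- if (!is.null(dosages) && !is.null(rownames(dosages))) rownames(dosages)
          else if (!is.null(hap_pairs) && !is.null(rownames(hap_pairs))) rownames(hap_pairs)
          else sprintf("S%05d", seq_len(n))
  comp <- function(w) { # vectorised additive component, missing dose -> 0
    if (!length(w)) return(list(v = rep(0, n), miss = rep(0L, n)))
    if (is.null(dosages))
      return(list(v = rep(0, n), miss = rep(length(w), n)))
    D <- matrix(NA_real_, n, length(w))
    have <- names(w) %in% colnames(dosages)
    D[, have] <- dosages[, names(w)[have], drop = FALSE]
    miss <- as.integer(rowSums(is.na(D)))
    D[is.na(D)] <- 0
    list(v = drop(D %*% unname(w)), miss = miss)
  }
  ho <- comp(model$hla_other)
  nh <- comp(model$non_hla)
  dq <- rep(0, n); path <- rep("additive", n); flagged <- rep(FALSE, n)
  if (length(model$dq_additive) || length(model$dq_interactions)) {
    if (is.null(hap_pairs)) {
      dq <- rep(NA_real_, n); path <- rep("unresolved", n); flagged <- rep(TRUE, n)
    } else {
      unres <- is.na(hap_pairs[, 1]) | is.na(hap_pairs[, 2])
      key <- pair_key(hap_pairs[, 1], hap_pairs[, 2])
      hit <- match(key, names(model$dq_interactions))
      w1 <- model$dq_additive[hap_pairs[, 1]]
      w2 <- model$dq_additive[hap_pairs[, 2]]
      dq <- ifelse(is.na(w1), 0, w1) + ifelse(is.na(w2), 0, w2)
      dq[!is.na(hit)] <- model$dq_interactions[hit[!is.na(hit)]]
      path[!is.na(hit)] <- "interaction_lookup"
      dq[unres] <- NA_real_; path[unres] <- "unresolved"; flagged[unres] <- TRUE
    }
  }
  out <- data.frame(iid = iids, total = dq + ho$v + nh$v, dq = dq,
                    hla_other = ho$v, non_hla = nh$v, dq_path = path,
                    flagged = flagged, n_missing_snps = ho$miss + nh$miss,
                    stringsAsFactors = FALSE)
  tot <- out$total[!is.na(out$total)]
  attr(out, "summary") <- list(
    median = stats::median(tot),
    iqr = unname(stats::quantile(tot, c(0.25, 0.75), type = 7)),
    tertiles = unname(stats::quantile(tot, c(1, 2) / 3, type = 7)),
    n_flagged = sum(out$flagged),
    missing_snp_entries = sum(out$n_missing_snps))
  class(out) <- c("score_result", class(out))
  out
}

#' Incremental SNP-addition AUC curve
#'
#' Starting from the DQ component alone, adds SNPs outside the DQ region
#' one at a time in ascending association p-value order and recomputes the
#' ROC AUC at each prefix, with a paired DeLong test between consecutive
#' curves. Monotone growth is not asserted; the first step whose AUC gain
#' is non-significant (p > `plateau_alpha`) marks the reported plateau.
#'
#' @param model A [build_model()] object (its DQ part is the base score).
#' @param hap_pairs,dosages As in [score_cohort()].
#' @param y 0/1 phenotype.
#' @param ranked_snps Character vector of SNP ids, best p first; default:
#'   model SNPs ordered as stored (which [build_model()] ranks by p).
#' @param plateau_alpha Paired DeLong significance level (default 0.05).
#' @return data.frame of class `incremental_auc`: `n_added snp auc
#'   p_vs_prev`, with attribute `plateau` (first plateau k, or NA).
#' @export
incremental_auc <- function(model, hap_pairs, dosages, y, ranked_snps = NULL,
                            plateau_alpha = 0.05) {
  if (is.null(ranked_snps)) ranked_snps <- c(names(model$hla_other), names(model$non_hla))
  base_model <- model
  base_model$hla_other <- numeric(0); base_model$non_hla <- numeric(0)
  base_model$effect_alleles <- character(0)
  score_with <- function(snps) {
    m <- base_model
    m$hla_other <- model$hla_other[intersect(snps, names(model$hla_other))]
    m$non_hla <- model$non_hla[intersect(snps, names(model$non_hla))]
    score_cohort(m, hap_pairs = hap_pairs, dosages = dosages)$total
  }
  prev <- score_with(character(0))
  out <- data.frame(n_added = 0L, snp = "", auc = roc_auc(prev, y)$auc,
                    p_vs_prev = NA_real_, stringsAsFactors = FALSE)
  plateau <- NA_integer_
  for (k in seq_along(ranked_snps)) {
    cur <- score_with(ranked_snps[seq_len(k)])
    dl <- delong_paired(cur, prev, y)
    out <- rbind(out, data.frame(n_added = k, snp = ranked_snps[k],
                                 auc = roc_auc(cur, y)$auc, p_vs_prev = dl$p,
                                 stringsAsFactors = FALSE))
    # plateau: the prefix size after which the next addition stops helping
    if (is.na(plateau) && dl$p > plateau_alpha) plateau <- k - 1L
    prev <- cur
  }
  attr(out, "plateau") <- plateau
  class(out) <- c("incremental_auc", class(out))
  out
}

#' Serialize a GRS model to schema-versioned JSON
#'
#' Also writes a flat interchange weight sheet
#' (`term_type id effect_allele beta`) next to the JSON when
#' `sheet = TRUE`.
#'
#' @param model A [build_model()] object.
#' @param path JSON output path.
#' @param sheet Write `<path>.weights.tsv` as well.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, sheet = FALSE) {
  obj <- list(version = model$version,
              dq_additive = as.list(model$dq_additive),
              dq_interactions = as.list(model$dq_interactions),
              hla_other = as.list(model$hla_other),
              non_hla = as.list(model$non_hla),
              effect_alleles = as.list(model$effect_alleles),
              metadata = model$metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  if (sheet) {
    utils::write.table(model_weights(model), paste0(path, ".weights.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Flat weight sheet of a GRS model
#'
#' @param model A [build_model()] object.
#' @return data.frame `term_type id effect_allele beta` (interaction rows
#'   carry the canonical pair key as id).
#' @export
model_weights <- function(model) {
  mk <- function(type, w) {
    if (!length(w)) return(NULL)
    ea <- model$effect_alleles[names(w)]
    data.frame(term_type = type, id = names(w),
               effect_allele = ifelse(is.na(ea), ".", ea), beta = unname(w),
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk("dq_additive", model$dq_additive),
               mk("dq_interaction", model$dq_interactions),
               mk("hla_other", model$hla_other),
               mk("non_hla", model$non_hla))
  if (is.null(out)) out <- data.frame(term_type = character(0), id = character(0),
                                      effect_allele = character(0), beta = numeric(0))
  out
}

#' Load a GRS model from JSON
#'
#' Unknown top-level fields raise a warning and are preserved under
#' `metadata$extra`; a schema version mismatch is an explicit error.
#'
#' @param path JSON path written by [save_model()].
#' @return A `grs_model` object.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stop_if_not(!is.null(obj$version), "model file has no schema version")
  stop_if_not(identical(obj$version, GRS_SCHEMA_VERSION),
              "model schema version %s not supported (expected %s)",
              obj$version, GRS_SCHEMA_VERSION)
  known <- c("version", "dq_additive", "dq_interactions", "hla_other",
             "non_hla", "effect_alleles", "metadata")
  extra <- setdiff(names(obj), known)
  md <- obj$metadata
  if (length(extra)) {
    warning(sprintf("unknown model field(s) preserved in metadata: %s",
                    paste(extra, collapse = ", ")))
    md$extra <- obj[extra]
  }
  num <- function(x) if (!length(x)) numeric(0) else unlist(x)
  chr <- function(x) if (!length(x)) character(0) else unlist(x)
  model <- list(dq_additive = num(obj$dq_additive),
                dq_interactions = num(obj$dq_interactions),
                hla_other = num(obj$hla_other),
                non_hla = num(obj$non_hla),
                effect_alleles = chr(obj$effect_alleles),
                metadata = md, version = obj$version)
  class(model) <- "grs_model"
  model
}

#' Re-import additive weights from a weight sheet
#'
#' @param path TSV written by [save_model()] / [model_weights()].
#' @return data.frame `term_type id effect_allele beta`.
#' @export
read_weights <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
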
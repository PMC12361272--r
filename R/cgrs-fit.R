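#' Fit an interaction-aware type 1 diabetes genetic risk score
#'
#' The central modelling entry point: from a case-control cohort it runs
#' the full construction pipeline and returns a fitted score model.
#' Steps: (1) SNP QC ([snp_qc()]); (2) marginal covariate screening at
#' p < 0.05 ([screen_covariates()]); (3) two-locus DQ haplotype inference
#' against a reference pool, chromosome-level frequency estimation with
#' the 0.5% filter, and per-haplotype additive logistic association;
#' (4) tag-SNP selection by phased r2/D' (or dosage-correlation fallback);
#' (5) per-haplogenotype multiplicative interaction tests with Bonferroni
#' filtering; (6) per-variant logistic GWAS of the remaining SNPs, with
#' non-HLA terms retained at genome-wide significance; (7) assembly of the
#' ln(OR)-weighted model ([build_model()]) and scoring of the training
#' cohort.
#'
#' @param cohort A `cohort` object ([simulate_cohort()] or
#'   [read_cohort()]).
#' @param pool_freq Named reference haplotype frequencies used for
#'   inference; default: the shipped Chinese DQ reference pool.
#' @param hla_p,nonhla_p Retention thresholds for other-HLA and non-HLA
#'   terms (defaults 4.72e-4 and 5e-8).
#' @param min_r2 Tag acceptance threshold (default 0.7).
#' @param min_carriers Haplogenotype carrier floor (default 10).
#' @param alpha Interaction significance level after Bonferroni (default
#'   0.05).
#' @param interaction_score `"full"` or `"gamma"` lookup composition.
#' @return Object of class `cgrs`: the fitted `grs_model` plus QC,
#'   association, haplotype, tag and interaction tables, training scores
#'   and training AUC.
#' @export
fit_cgrs <- function(cohort, pool_freq = NULL, hla_p = 4.72e-4,
                     nonhla_p = 5e-8, min_r2 = 0.7, min_carriers = 10L,
                     alpha = 0.05, interaction_score = c("full", "gamma")) {
  interaction_score <- match.arg(interaction_score)
  y <- cohort$phenotype
  if (is.null(pool_freq)) {
    pool <- default_haplotype_pool()
    pool_freq <- stats::setNames(pool$freq, pool$label)
  }

  qc <- snp_qc(cohort$genotypes, phenotype = y)
  covs <- screen_covariates(y, cohort$covariates)
  C <- if (length(covs)) cohort$covariates[, covs, drop = FALSE] else NULL

  pairs <- infer_haplogenotypes(cohort$hla, pool_freq)
  freqs <- haplotype_frequencies(pairs, y)
  kept_labels <- freqs$label[freqs$kept]
  hd <- haplotype_dosages(pairs, labels = kept_labels)

  # additive per-haplotype association (dose + screened covariates)
  dq_assoc <- do.call(rbind, lapply(kept_labels, function(lab) {
    X <- cbind(dose = hd[, lab], if (!is.null(C)) as.matrix(C))
    ok <- stats::complete.cases(X)
    fit <- fit_logistic(y[ok], X[ok, , drop = FALSE])
    data.frame(label = lab, beta = fit$beta[2], se = fit$se[2], p = fit$p[2],
               or = exp(fit$beta[2]), stringsAsFactors = FALSE)
  }))

  # tag selection: phased truth when carried by the cohort, else dosages
  tag_candidates <- cohort$genotypes$variants$id[cohort$genotypes$variants$chr == "6"]
  tags <- NULL
  if (length(tag_candidates) && length(kept_labels)) {
    positions <- stats::setNames(cohort$genotypes$variants$pos,
                                 cohort$genotypes$variants$id)
    hap_data <- if (!is.null(cohort$tag_alleles) && !is.null(cohort$phased)) {
      list(chrom = as.vector(t(cohort$phased)),
           alleles = cohort$tag_alleles[, intersect(tag_candidates,
                                                    colnames(cohort$tag_alleles)),
                                        drop = FALSE])
    } else {
      list(hap_doses = hd, snp_doses = cohort$genotypes$dosage[, tag_candidates,
                                                               drop = FALSE])
    }
    cand <- if (!is.null(hap_data$alleles)) colnames(hap_data$alleles) else tag_candidates
    if (length(cand))
      tags <- select_tags(freqs, cand, hap_data, positions = positions,
                          min_r2 = min_r2)
  }

  pairs_tab <- enumerate_haplogenotypes(hd, min_carriers = min_carriers)
  inter <- do.call(rbind, lapply(seq_len(nrow(pairs_tab)), function(i) {
    fit_interaction(y, hd, c(pairs_tab$hapA[i], pairs_tab$hapB[i]),
                    covariates = C)
  }))
  inter_tab <- if (is.null(inter)) NULL else
    significant_interactions(inter, alpha = alpha, score = interaction_score)

  # HLA SNPs outside DQ: association adjusted for DQ haplotype dosages
  # (reference haplotype dropped; dosage rows sum to 2, so the full set is
  # collinear with the intercept)
  tag_ids <- if (is.null(tags)) character(0) else tags$snp[tags$tagged]
  hla_other_ids <- setdiff(tag_candidates, tag_ids)
  hla_other_assoc <- NULL
  if (length(hla_other_ids) && length(kept_labels) > 1) {
    ctrl_freq <- colMeans(hd[y == 0L, , drop = FALSE], na.rm = TRUE)
    ref <- kept_labels[which.max(ctrl_freq)]
    hd_adj <- hd[, setdiff(kept_labels, ref), drop = FALSE]
    keep <- cohort$genotypes$variants$id %in% hla_other_ids
    sub <- geno_matrix(cohort$genotypes$dosage[, keep, drop = FALSE],
                       cohort$genotypes$variants[keep, , drop = FALSE])
    Cdq <- cbind(if (!is.null(C)) as.matrix(C), hd_adj)
    ok <- stats::complete.cases(Cdq)
    sub_ok <- geno_matrix(sub$dosage[ok, , drop = FALSE], sub$variants)
    hla_other_assoc <- run_gwas(sub_ok, y[ok], covariates = Cdq[ok, , drop = FALSE],
                                qc = qc)
  }

  # non-HLA GWAS over QC-passing variants off chromosome 6
  nonhla_ids <- cohort$genotypes$variants$id[cohort$genotypes$variants$chr != "6"]
  nonhla_assoc <- NULL
  if (length(nonhla_ids)) {
    keep <- cohort$genotypes$variants$id %in% nonhla_ids
    sub <- geno_matrix(cohort$genotypes$dosage[, keep, drop = FALSE],
                       cohort$genotypes$variants[keep, , drop = FALSE])
    nonhla_assoc <- run_gwas(sub, y, covariates = C, qc = qc)
  }

  model <- build_model(dq_assoc = dq_assoc, interaction_table = inter_tab,
                       hla_other_assoc = hla_other_assoc,
                       non_hla_assoc = nonhla_assoc,
                       hla_p = hla_p, nonhla_p = nonhla_p,
                       metadata = list(n_cases = sum(y == 1L),
                                       n_controls = sum(y == 0L),
                                       covariates = covs))

  hap_pairs <- as.matrix(pairs[, c("hap1", "hap2")])
  rownames(hap_pairs) <- pairs$iid
  scores <- score_cohort(model, hap_pairs = hap_pairs,
                         dosages = cohort$genotypes$dosage)
  roc <- roc_auc(scores$total, y)

  fitobj <- list(model = model, qc = qc, covariates = covs,
                 haplotype_pairs = pairs, haplotype_freqs = freqs,
                 dq_assoc = dq_assoc, tags = tags, interactions = inter,
                 interaction_table = inter_tab,
                 hla_other_assoc = hla_other_assoc, nonhla_assoc = nonhla_assoc,
                 scores = scores, roc = roc, phenotype = y)
  class(fitobj) <- "cgrs"
  fitobj
}

#' @export
print.cgrs <- function(x, ...) {
  cat("Interaction-aware GRS fit\n")
  print(x$model)
  cat(sprintf("  training AUC: %.4f (%d cases / %d controls)\n",
              x$roc$auc, x$roc$n_pos, x$roc$n_neg))
  invisible(x)
}

#' @export
summary.cgrs <- function(object, ...) {
  cat("Interaction-aware GRS fit\n\n")
  cat(sprintf("QC: %d of %d variants kept\n", sum(object$qc$kept),
              nrow(object$qc)))
  cat(sprintf("Screened covariates: %s\n",
              if (length(object$covariates)) paste(object$covariates, collapse = ", ")
              else "none"))
  cat(sprintf("DQ haplotypes kept (freq > 0.5%% in both groups): %d\n",
              sum(object$haplotype_freqs$kept)))
  if (!is.null(object$tags)) {
    cat(sprintf("Tagged haplotypes (r2 >= %.2f): %d of %d\n",
                attr(object$tags, "min_r2"), sum(object$tags$tagged),
                nrow(object$tags)))
  }
  cat(sprintf("Significant haplogenotype interactions: %d\n",
              if (is.null(object$interaction_table)) 0L
              else nrow(object$interaction_table)))
  cat(sprintf("Non-HLA SNPs retained: %d\n", length(object$model$non_hla)))
  cat(sprintf("\nTraining AUC %.4f, PRAUC %.4f\n", object$roc$auc,
              pr_auc(object$scores$total, object$phenotype)))
  invisible(object)
}

#' @export
coef.cgrs <- function(object, ...) {
  w <- model_weights(object$model)
  stats::setNames(w$beta, paste(w$term_type, w$id, sep = ":"))
}

#' Score new individuals with a fitted GRS
#'
#' @param object A [fit_cgrs()] object.
#' @param newdata A `cohort` object; its HLA typing is phased against the
#'   same reference pool used at fit time when phased truth is absent.
#' @param pool_freq Reference pool frequencies for haplotype inference of
#'   `newdata` (default: shipped reference pool).
#' @param ... Unused.
#' @return A [score_cohort()] data.frame.
#' @export
predict.cgrs <- function(object, newdata = NULL, pool_freq = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  if (is.null(pool_freq)) {
    pool <- default_haplotype_pool()
    pool_freq <- stats::setNames(pool$freq, pool$label)
  }
  hap_pairs <- NULL
  if (!is.null(newdata$hla)) {
    pairs <- infer_haplogenotypes(newdata$hla, pool_freq)
    hap_pairs <- as.matrix(pairs[, c("hap1", "hap2")])
    rownames(hap_pairs) <- pairs$iid
  }
  score_cohort(object$model, hap_pairs = hap_pairs,
               dosages = if (is.null(newdata$genotypes)) NULL
                         else newdata$genotypes$dosage)
}

#' @export
plot.cgrs <- function(x, ...) {
  graphics::plot(x$roc, main = sprintf("Training ROC (AUC = %.3f)", x$roc$auc),
                 ...)
}
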
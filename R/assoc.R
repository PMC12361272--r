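#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test on hard genotype counts: given the
#' allele counts, the p-value is the sum of probabilities of all
#' heterozygote counts whose conditional probability does not exceed that
#' of the observed count. Monomorphic input returns p = 1.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (major hom, het, minor hom);
#'   the test is symmetric in `n_aa` and `n_bb`.
#' @return Two-sided exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stop_if_not(all(c(n_aa, n_ab, n_bb) >= 0), "genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  stop_if_not(n > 0, "all genotype counts are zero")
  nA <- 2L * n_aa + n_ab
  nB <- 2L * n_bb + n_ab
  if (nA == 0L || nB == 0L) return(1)
  nmin <- min(nA, nB)
  # heterozygote counts share the parity of the minor allele count
  hets <- seq(nmin %% 2L, nmin, by = 2L)
  # log P(n_ab = h | n, nA) = log[ n! nA! nB! 2^h / ((2n)! nAA! h! nBB!) ]
  logp <- lgamma(n + 1) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1) +
    hets * log(2) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((nB - hets) / 2 + 1)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_ab, hets)]
  stop_if_not(!is.na(obs), "heterozygote count inconsistent with allele counts")
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' Per-variant SNP quality control
#'
#' Flags variants that are monomorphic, below the MAF threshold, out of
#' Hardy-Weinberg equilibrium (exact test on dosages hard-called to the
#' nearest integer, evaluated in controls when a phenotype is supplied),
#' or above the missingness threshold. MAF is computed on non-missing
#' dosages. A variant is kept iff no reason applies.
#'
#' @param geno A [geno_matrix()].
#' @param phenotype Optional 0/1 vector; HWE is then tested in controls
#'   only (standard practice for case-control panels).
#' @param maf_min MAF threshold (exclusive; default 0.05). 0 disables.
#' @param hwe_p HWE p-value threshold (default 1e-4). 0 disables.
#' @param miss_max Missingness threshold (default 0.05). 1 disables.
#' @param drop_monomorphic Flag monomorphic variants (default TRUE).
#' @return data.frame of class `qc_report`: `id`, `maf`, `miss_rate`,
#'   `hwe_p`, `reasons` (comma-joined), `kept`; thresholds as attributes.
#' @export
snp_qc <- function(geno, phenotype = NULL, maf_min = 0.05, hwe_p = 1e-4,
                   miss_max = 0.05, drop_monomorphic = TRUE) {
  stop_if_not(inherits(geno, "geno_matrix"), "geno must be a geno_matrix")
  stop_if_not(ncol(geno$dosage) > 0 && nrow(geno$dosage) > 0, "empty genotype matrix")
  D <- geno$dosage
  hwe_rows <- if (is.null(phenotype)) seq_len(nrow(D)) else which(phenotype == 0L)
  res <- lapply(seq_len(ncol(D)), function(j) {
    d <- D[, j]
    miss <- mean(is.na(d))
    dn <- d[!is.na(d)]
    af <- if (length(dn)) mean(dn) / 2 else NA_real_
    maf <- min(af, 1 - af)
    mono <- length(dn) == 0L || length(unique(dn)) == 1L
    hw <- NA_real_
    if (!mono) {
      hc <- round(D[hwe_rows, j])
      hc <- hc[!is.na(hc)]
      if (length(hc))
        hw <- hwe_exact_test(sum(hc == 0), sum(hc == 1), sum(hc == 2))
    }
    reasons <- character(0)
    if (drop_monomorphic && mono) reasons <- c(reasons, "monomorphic")
    if (maf_min > 0 && !mono && maf < maf_min) reasons <- c(reasons, "low_maf")
    if (hwe_p > 0 && !is.na(hw) && hw < hwe_p) reasons <- c(reasons, "hwe_fail")
    if (miss > miss_max) reasons <- c(reasons, "high_missing")
    list(maf = maf, miss = miss, hw = hw, reasons = paste(reasons, collapse = ","))
  })
  out <- data.frame(
    id = geno$variants$id,
    maf = vapply(res, `[[`, 0, "maf"),
    miss_rate = vapply(res, `[[`, 0, "miss"),
    hwe_p = vapply(res, `[[`, 0, "hw"),
    reasons = vapply(res, `[[`, "", "reasons"),
    stringsAsFactors = FALSE)
  out$kept <- out$reasons == ""
  attr(out, "thresholds") <- c(maf_min = maf_min, hwe_p = hwe_p,
                               miss_max = miss_max)
  class(out) <- c("qc_report", class(out))
  out
}

#' Maximum-likelihood logistic regression with separation reporting
#'
#' Fits `y ~ X` with an intercept by iteratively reweighted least squares
#' (via [stats::glm.fit()]). Non-convergence or (quasi-)separation is
#' reported in the `flagged` attribute with a diagnostic, and no numeric
#' estimates are returned for flagged fits.
#'
#' @param y 0/1 response with at least one case and one control.
#' @param X Numeric matrix or data.frame of predictors (no intercept
#'   column).
#' @return data.frame (`term`, `beta`, `se`, `z`, `p`) with attributes
#'   `flagged` (logical) and `diagnostic` (character).
#' @export
fit_logistic <- function(y, X) {
  y <- as.numeric(y)
  stop_if_not(any(y == 1) && any(y == 0), "need at least one case and one control")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(
    stats::glm.fit(Xi, y, family = stats::binomial(), control = stats::glm.control(maxit = 50)))
  out <- data.frame(term = colnames(Xi), beta = NA_real_, se = NA_real_,
                    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  flagged <- FALSE; diagnostic <- ""
  mu <- fit$fitted.values
  if (!fit$converged) {
    flagged <- TRUE; diagnostic <- "IRLS did not converge"
  } else if (any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    flagged <- TRUE; diagnostic <- "fitted probabilities numerically 0 or 1 (separation)"
  } else {
    qrr <- fit$qr
    rank <- qrr$rank
    cov <- tryCatch(chol2inv(qrr$qr[seq_len(rank), seq_len(rank), drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(cov)) {
      flagged <- TRUE; diagnostic <- "singular information matrix"
    } else {
      # aliased (rank-deficient) columns keep NA estimates, as in glm()
      piv <- qrr$pivot[seq_len(rank)]
      out$beta <- unname(fit$coefficients[out$term])
      out$se[piv] <- sqrt(diag(cov))
      if (rank < ncol(Xi))
        diagnostic <- sprintf("aliased column(s): %s",
                              paste(colnames(Xi)[qrr$pivot[-seq_len(rank)]],
                                    collapse = ", "))
      if (any(out$se > 50, na.rm = TRUE)) {
        flagged <- TRUE
        diagnostic <- "unstable standard errors (quasi-separation)"
        out$beta <- out$se <- NA_real_
      } else {
        out$z <- out$beta / out$se
        out$p <- 2 * stats::pnorm(-abs(out$z))
      }
    }
  }
  attr(out, "flagged") <- flagged
  attr(out, "diagnostic") <- diagnostic
  out
}

#' Marginal covariate screen for association models
#'
#' Fits the case-control response against each covariate alone and retains,
#' in input order, those with Wald p < `alpha` (default 0.05). Constant or
#' separation-flagged covariates are excluded with a warning.
#'
#' @param y 0/1 response.
#' @param covariates data.frame aligned to `y`.
#' @param alpha Inclusion threshold.
#' @return Character vector of selected covariate names (possibly empty),
#'   with per-covariate p-values in attribute `p`.
#' @export
screen_covariates <- function(y, covariates, alpha = 0.05) {
  stop_if_not(nrow(covariates) == length(y), "covariates not aligned to response")
  p <- stats::setNames(rep(NA_real_, ncol(covariates)), colnames(covariates))
  for (j in seq_len(ncol(covariates))) {
    x <- as.numeric(covariates[[j]])
    if (length(unique(x[!is.na(x)])) < 2L) next
    fit <- fit_logistic(y, matrix(x, ncol = 1, dimnames = list(NULL, colnames(covariates)[j])))
    if (attr(fit, "flagged")) {
      warning(sprintf("covariate %s excluded: %s", colnames(covariates)[j],
                      attr(fit, "diagnostic")))
      next
    }
    p[j] <- fit$p[2]
  }
  sel <- colnames(covariates)[!is.na(p) & p < alpha]
  attr(sel, "p") <- p
  sel
}

#' Per-variant case-control logistic association
#'
#' One logistic regression per QC-passing variant, with per-variant missing
#' dosages mean-imputed and screened covariates adjusted for. Reports the
#' per-allele log-odds `beta`, `or = exp(beta)`, Wald 95% CI and p-value,
#' MAF and sample size; significance tiers (suggestive p < 1e-5,
#' genome-wide p < 5e-8) are annotated, never filtered. Fit failures
#' propagate as flagged rows with a note.
#'
#' @param geno A [geno_matrix()].
#' @param y 0/1 phenotype aligned to the rows of `geno`.
#' @param covariates Optional data.frame of pre-screened covariates.
#' @param qc Optional [snp_qc()] report; only kept variants are tested.
#' @return data.frame of class `assoc_result`: `id chr pos a1 a2 maf beta
#'   se or ci_low ci_high p n sig note`.
#' @export
run_gwas <- function(geno, y, covariates = NULL, qc = NULL) {
  stop_if_not(inherits(geno, "geno_matrix"), "geno must be a geno_matrix")
  stop_if_not(nrow(geno$dosage) == length(y), "phenotype not aligned to genotypes")
  keep <- if (is.null(qc)) rep(TRUE, ncol(geno$dosage)) else
    qc$kept[match(geno$variants$id, qc$id)]
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  rows <- lapply(which(keep), function(j) {
    d <- geno$dosage[, j]
    if (anyNA(d)) d[is.na(d)] <- mean(d, na.rm = TRUE)
    af <- mean(d) / 2
    X <- cbind(dose = d, C)
    fit <- fit_logistic(y, X)
    b <- fit$beta[2]; se <- fit$se[2]; p <- fit$p[2]
    note <- if (attr(fit, "flagged")) attr(fit, "diagnostic") else ""
    if (attr(fit, "flagged")) b <- se <- p <- NA_real_
    data.frame(id = geno$variants$id[j], chr = geno$variants$chr[j],
               pos = geno$variants$pos[j], a1 = geno$variants$a1[j],
               a2 = geno$variants$a2[j], maf = min(af, 1 - af),
               beta = b, se = se, or = exp(b),
               ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
               p = p, n = length(y), note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$sig <- ifelse(is.na(out$p), "",
             ifelse(out$p < 5e-8, "genome_wide",
             ifelse(out$p < 1e-5, "suggestive", "")))
  class(out) <- c("assoc_result", class(out))
  out
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)`: the
#' ratio of the median observed association chi-squared statistic to the
#' null median (0.4549364), quantifying systematic test inflation.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return lambda.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  stop_if_not(length(p_values) > 0, "no p-values supplied")
  stop_if_not(all(p_values > 0 & p_values <= 1), "p-values must lie in (0, 1]")
  stats::median(stats::qchisq(p_values, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Inverse-variance fixed-effect meta-analysis of association results
#'
#' Pools per-variant log-odds across cohorts with weights `w = 1/SE^2`:
#' `beta = sum(w b) / sum(w)`, `SE = 1/sqrt(sum(w))`, two-sided Wald p.
#' Effect alleles are aligned to the first cohort: a variant whose a1/a2
#' are swapped in a later cohort has its sign flipped; any other allele
#' mismatch aborts with a per-variant diagnostic.
#'
#' @param results List of >= 2 [run_gwas()] tables sharing variants.
#' @return data.frame of class `meta_result`: `id beta se z p n_cohorts`,
#'   with per-cohort inputs in attribute `inputs`.
#' @export
meta_fixed <- function(results) {
  stop_if_not(is.list(results) && length(results) >= 2, "need >= 2 cohorts")
  base <- results[[1]]
  ids <- base$id
  for (k in seq_along(results)[-1]) ids <- intersect(ids, results[[k]]$id)
  stop_if_not(length(ids) > 0, "no shared variants across cohorts")
  rows <- lapply(ids, function(v) {
    b <- se <- numeric(length(results))
    ref <- base[base$id == v, ]
    for (k in seq_along(results)) {
      r <- results[[k]][results[[k]]$id == v, ]
      flip <- 1
      if (!identical(c(r$a1, r$a2), c(ref$a1, ref$a2))) {
        if (identical(c(r$a1, r$a2), c(ref$a2, ref$a1))) flip <- -1
        else stop(sprintf("allele mismatch for %s in cohort %d: %s/%s vs %s/%s",
                          v, k, r$a1, r$a2, ref$a1, ref$a2), call. = FALSE)
      }
      b[k] <- flip * r$beta; se[k] <- r$se
    }
    w <- 1 / se^2
    pooled_b <- sum(w * b) / sum(w)
    pooled_se <- 1 / sqrt(sum(w))
    z <- pooled_b / pooled_se
    data.frame(id = v, beta = pooled_b, se = pooled_se, z = z,
               p = 2 * stats::pnorm(-abs(z)), n_cohorts = length(results),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "inputs") <- results
  class(out) <- c("meta_result", class(out))
  out
}
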
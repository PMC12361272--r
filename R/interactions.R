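#' Enumerate candidate haplogenotypes with a carrier floor
#'
#' All unordered pairs of haplotype labels (including homozygous pairs)
#' carried by at least `min_carriers` individuals. A carrier of a
#' heterozygous pair has dose >= 1 of both haplotypes (dose product >= 1);
#' a carrier of a homozygous pair has dose 2.
#'
#' @param hap_doses [haplotype_dosages()] matrix.
#' @param min_carriers Minimum carrier count (default 10, guards against
#'   separation in the interaction fit).
#' @return data.frame `hapA`, `hapB` (canonical `hapA <= hapB`),
#'   `n_carriers`.
#' @export
enumerate_haplogenotypes <- function(hap_doses, min_carriers = 10L) {
  labs <- sort(colnames(hap_doses))
  rows <- list()
  for (i in seq_along(labs)) for (j in i:length(labs)) {
    A <- labs[i]; B <- labs[j]
    carriers <- if (A == B) sum(hap_doses[, A] == 2, na.rm = TRUE)
                else sum(hap_doses[, A] >= 1 & hap_doses[, B] >= 1, na.rm = TRUE)
    if (carriers >= min_carriers)
      rows[[length(rows) + 1L]] <- data.frame(hapA = A, hapB = B,
                                              n_carriers = carriers,
                                              stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(hapA = character(0), hapB = character(0),
                      n_carriers = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Multiplicative haplogenotype interaction term
#'
#' Heterozygous pair: the product of the two haplotype doses. Homozygous
#' pair: an indicator of dose 2 (a product coding of 4 would conflate with
#' the additive dose). Symmetric in its arguments.
#'
#' @param dose_a,dose_b Haplotype doses in \{0, 1, 2\} (vectorised).
#' @param homozygous TRUE when the pair is a haplotype with itself, in
#'   which case `dose_a` and `dose_b` are the same column.
#' @return Numeric term values.
#' @export
interaction_term <- function(dose_a, dose_b, homozygous = FALSE) {
  if (homozygous) as.numeric(dose_a == 2) else dose_a * dose_b
}

#' Test one haplogenotype's multiplicative interaction
#'
#' Logistic regression of case status on main-effect dose columns for all
#' kept haplotypes (the reference haplotype's column dropped for
#' identifiability), screened covariates, and the pair's interaction term;
#' returns the Wald test on the interaction coefficient together with the
#' haplogenotype's full fitted log-odds (main effects plus gamma), the
#' default lookup score of the risk model. Separation or non-convergence
#' is flagged, never silent.
#'
#' @param y 0/1 phenotype.
#' @param hap_doses [haplotype_dosages()] matrix over kept haplotypes.
#' @param pair Character length-2: the haplotype labels (equal for a
#'   homozygous pair).
#' @param covariates Optional data.frame of screened covariates.
#' @param reference Reference haplotype label whose main-effect column is
#'   dropped; default: the most frequent haplotype among controls.
#' @return One-row data.frame: `hapA hapB gamma se or p score flagged
#'   note`.
#' @export
fit_interaction <- function(y, hap_doses, pair, covariates = NULL,
                            reference = NULL) {
  labs <- colnames(hap_doses)
  stop_if_not(all(pair %in% labs), "pair references unknown haplotype labels")
  if (is.null(reference)) {
    ctrl_freq <- colMeans(hap_doses[y == 0, , drop = FALSE], na.rm = TRUE)
    reference <- labs[which.max(ctrl_freq)]
  }
  A <- min(pair); B <- max(pair)
  homo <- A == B
  term <- interaction_term(hap_doses[, A], hap_doses[, B], homozygous = homo)
  main <- hap_doses[, setdiff(labs, reference), drop = FALSE]
  X <- cbind(main, if (!is.null(covariates)) as.matrix(covariates),
             interaction = term)
  ok <- stats::complete.cases(X) & !is.na(y)
  out <- data.frame(hapA = A, hapB = B, gamma = NA_real_, se = NA_real_,
                    or = NA_real_, p = NA_real_, score = NA_real_,
                    flagged = FALSE, note = "", stringsAsFactors = FALSE)
  if (length(unique(term[ok])) < 2L) {
    out$flagged <- TRUE
    out$note <- "interaction term constant in sample"
    return(out)
  }
  fit <- fit_logistic(y[ok], X[ok, , drop = FALSE])
  if (attr(fit, "flagged")) {
    out$flagged <- TRUE
    out$note <- attr(fit, "diagnostic")
    return(out)
  }
  i <- which(fit$term == "interaction")
  out$gamma <- fit$beta[i]; out$se <- fit$se[i]
  out$or <- exp(out$gamma); out$p <- fit$p[i]
  # full haplogenotype log-odds relative to reference homozygotes:
  # main effects at carrier doses plus gamma at term = 1
  coefs <- stats::setNames(fit$beta, fit$term)
  mb <- function(h) if (h == reference) 0 else unname(coefs[h])
  out$score <- if (homo) 2 * mb(A) + out$gamma else mb(A) + mb(B) + out$gamma
  attr(out, "reference") <- reference
  out
}

#' Filter interaction results into a lookup score table
#'
#' Applies a multiplicity correction over the tested pairs (default
#' Bonferroni via [stats::p.adjust()]; `"none"` or `"fdr"` are accepted)
#' and keeps unflagged pairs with corrected p < `alpha`. The returned
#' table maps canonical haplogenotype keys to lookup scores consumed by
#' [build_model()].
#'
#' @param results Row-bound [fit_interaction()] results.
#' @param alpha Significance level (default 0.05).
#' @param correction `"bonferroni"` (default), `"fdr"` or `"none"`.
#' @param score `"full"` (default; fitted haplogenotype log-odds) or
#'   `"gamma"` (the interaction coefficient alone) as the lookup value.
#' @return data.frame `hapA hapB key gamma se or p p_adj score
#'   significant`, subset to significant rows in attribute-free form.
#' @export
significant_interactions <- function(results, alpha = 0.05,
                                     correction = c("bonferroni", "fdr", "none"),
                                     score = c("full", "gamma")) {
  correction <- match.arg(correction)
  score <- match.arg(score)
  if (!nrow(results)) {
    return(data.frame(hapA = character(0), hapB = character(0),
                      key = character(0), gamma = numeric(0), se = numeric(0),
                      or = numeric(0), p = numeric(0), p_adj = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  results$p_adj <- stats::p.adjust(results$p,
                                   method = if (correction == "none") "none" else correction)
  keep <- !results$flagged & !is.na(results$p_adj) & results$p_adj < alpha
  out <- results[keep, , drop = FALSE]
  out$key <- pair_key(out$hapA, out$hapB)
  if (score == "gamma") out$score <- out$gamma
  rownames(out) <- NULL
  out[, c("hapA", "hapB", "key", "gamma", "se", "or", "p", "p_adj", "score")]
}
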
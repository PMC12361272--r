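# Replicated simulation studies used to validate the estimators. These are
# the package's own evaluation experiments: each returns raw replicate
# values so callers can form Monte-Carlo errors.

#' Single-SNP effect-size recovery study
#'
#' Simulates case-control cohorts containing one additive SNP at the given
#' MAF and per-allele log-odds, fits the single-SNP logistic regression in
#' each replicate, and returns the estimates. Logistic slopes are
#' invariant under case-control (outcome-dependent) sampling, so the mean
#' estimate recovers the generating beta.
#'
#' @param maf,beta Generating minor allele frequency and log-odds.
#' @param n_cases,n_controls Cohort quotas per replicate.
#' @param reps Number of replicates.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param intercept Baseline log-odds of the generating model.
#' @return List: `beta_hat` (vector), `mean`, `se_mc` (Monte-Carlo
#'   standard error of the mean).
#' @export
snp_beta_recovery <- function(maf, beta, n_cases = 1300L, n_controls = 2200L,
                              reps = 200L, seed = 1L, intercept = -0.6) {
  beta_hat <- vapply(seq_len(reps), function(r) {
    cfg <- sim_config(n_cases = n_cases, n_controls = n_controls,
                      haplotype_pool = NULL, interaction_effects = NULL,
                      tag_specs = NULL,
                      nonhla_snps = data.frame(id = "snp", chr = "1", pos = 1L,
                                               maf = maf, beta = beta),
                      sex_beta = 0, pc_betas = numeric(0),
                      intercept = intercept, missing_rate = 0,
                      seed = seed + r)
    co <- simulate_cohort(cfg)
    fit <- fit_logistic(co$phenotype,
                        matrix(co$genotypes$dosage[, 1], ncol = 1,
                               dimnames = list(NULL, "dose")))
    fit$beta[2]
  }, numeric(1))
  list(beta_hat = beta_hat, mean = mean(beta_hat),
       se_mc = stats::sd(beta_hat) / sqrt(reps))
}

#' Type-I error of the per-SNP Wald test under the null
#'
#' Draws independent Binomial(2, MAF) dosages against a fixed balanced
#' phenotype and records the single-SNP Wald p-value per replicate.
#'
#' @param reps Replicates (independent null SNPs).
#' @param n Sample size per replicate (half cases).
#' @param maf Null SNP allele frequency.
#' @param seed Seed.
#' @return List: `p` (vector of p-values), `rejection_rate` at alpha =
#'   0.05.
#' @export
wald_type1_study <- function(reps = 2000L, n = 3000L, maf = 0.3, seed = 1L) {
  with_seed(seed, {
    y <- rep(c(1L, 0L), length.out = n)
    p <- vapply(seq_len(reps), function(r) {
      x <- stats::rbinom(n, 2L, maf)
      fit_logistic(y, matrix(x, ncol = 1, dimnames = list(NULL, "dose")))$p[2]
    }, numeric(1))
    list(p = p, rejection_rate = mean(p < 0.05))
  })
}

# shared by the interaction null and recovery studies
interaction_gamma_reps <- function(gamma, pair_idx, reps, n_cases, n_controls,
                                   seed, intercept = -1.3) {
  pool <- default_haplotype_pool()
  pair <- pool$label[pair_idx]
  effs <- if (gamma == 0) NULL else stats::setNames(gamma, pair_key(pair[1], pair[2]))
  res <- vapply(seq_len(reps), function(r) {
    cfg <- sim_config(n_cases = n_cases, n_controls = n_controls,
                      haplotype_pool = pool, interaction_effects = effs,
                      tag_specs = NULL, nonhla_snps = NULL,
                      intercept = intercept, missing_rate = 0, seed = seed + r)
    co <- simulate_cohort(cfg)
    ph <- co$phased
    pairs <- data.frame(iid = rownames(ph), hap1 = pmin(ph[, 1], ph[, 2]),
                        hap2 = pmax(ph[, 1], ph[, 2]), resolved = TRUE,
                        stringsAsFactors = FALSE)
    hd <- haplotype_dosages(pairs, labels = pool$label)
    fit <- fit_interaction(co$phenotype, hd, pair, covariates = co$covariates)
    c(fit$gamma, fit$p, fit$flagged)
  }, numeric(3))
  list(gamma_hat = res[1, ], p = res[2, ], flagged = res[3, ] == 1)
}

#' Type-I error of the haplogenotype interaction test
#'
#' Simulates cohorts from the default haplotype pool with all interaction
#' effects zero (main haplotype effects and covariate effects active) and
#' tests one common haplogenotype's multiplicative term per replicate.
#'
#' @param reps Replicates.
#' @param n_cases,n_controls Quotas per replicate.
#' @param seed Seed.
#' @param pair_idx Indices into the default pool of the tested pair.
#' @return List: `p`, `gamma_hat`, `rejection_rate` at alpha = 0.05
#'   (flagged replicates excluded and counted).
#' @export
interaction_type1_study <- function(reps = 1000L, n_cases = 600L,
                                    n_controls = 900L, seed = 1L,
                                    pair_idx = c(1L, 8L)) {
  r <- interaction_gamma_reps(0, pair_idx, reps, n_cases, n_controls, seed)
  ok <- !r$flagged & !is.na(r$p)
  list(p = r$p[ok], gamma_hat = r$gamma_hat[ok], n_flagged = sum(!ok),
       rejection_rate = mean(r$p[ok] < 0.05))
}

#' Interaction effect recovery study
#'
#' Plants a single haplogenotype interaction of size `gamma` and measures
#' the mean fitted interaction coefficient across replicates.
#'
#' @inheritParams interaction_type1_study
#' @param gamma Generating interaction log-odds.
#' @return List: `gamma_hat`, `mean`, `se_mc`.
#' @export
interaction_recovery_study <- function(gamma = 0.8, reps = 200L,
                                       n_cases = 1500L, n_controls = 1500L,
                                       seed = 1L, pair_idx = c(1L, 3L)) {
  r <- interaction_gamma_reps(gamma, pair_idx, reps, n_cases, n_controls, seed)
  ok <- !r$flagged & !is.na(r$gamma_hat)
  list(gamma_hat = r$gamma_hat[ok], mean = mean(r$gamma_hat[ok]),
       se_mc = stats::sd(r$gamma_hat[ok]) / sqrt(sum(ok)),
       n_flagged = sum(!ok))
}

#' Type-I error of the paired DeLong test
#'
#' Two independent uninformative scores on the same individuals per
#' replicate.
#'
#' @param reps Replicates.
#' @param n_pos,n_neg Group sizes.
#' @param seed Seed.
#' @return List: `p`, `rejection_rate` at alpha = 0.05.
#' @export
delong_type1_study <- function(reps = 1000L, n_pos = 150L, n_neg = 150L,
                               seed = 1L) {
  with_seed(seed, {
    labels <- rep(c(1L, 0L), c(n_pos, n_neg))
    p <- vapply(seq_len(reps), function(r) {
      a <- stats::rnorm(n_pos + n_neg)
      b <- stats::rnorm(n_pos + n_neg)
      delong_paired(a, b, labels)$p
    }, numeric(1))
    list(p = p, rejection_rate = mean(p < 0.05))
  })
}

#' Planted tag-SNP recovery study
#'
#' Simulates a large null cohort (no effects), plants tag SNPs at the
#' requested r-squared targets for the first haplotypes of the default
#' pool, and runs [select_tags()] over the planted tags. The sampling
#' error of the measured phased r-squared is estimated by
#' simulate-and-measure: `se_reps` further independent tag emissions on
#' the same chromosomes give the conditional standard deviation of the
#' realized r-squared around its target.
#'
#' @param targets Named or unnamed target r-squared values (assigned to
#'   the first `length(targets)` pool haplotypes when unnamed).
#' @param n_individuals Cohort size (chromosomes = 2n).
#' @param seed Seed.
#' @param se_reps Replicate emissions used for the empirical SE.
#' @return data.frame `label target snp r2 se tagged correct` where
#'   `correct` flags that the planted tag was the one selected and `se`
#'   is the empirical SE of `r2`.
#' @export
tag_recovery_study <- function(targets = c(1.0, 0.9, 0.8),
                               n_individuals = 50000L, seed = 1L,
                               se_reps = 30L) {
  pool <- default_haplotype_pool()
  if (is.null(names(targets)))
    names(targets) <- pool$label[seq_along(targets)]
  pool0 <- pool; pool0$beta <- 0
  cfg <- sim_config(n_cases = ceiling(n_individuals / 2),
                    n_controls = floor(n_individuals / 2),
                    haplotype_pool = pool0, interaction_effects = NULL,
                    tag_specs = targets, intercept = 0, missing_rate = 0,
                    seed = seed)
  co0 <- simulate_cohort(cfg)
  co <- emit_tag_snps(co0)
  chrom <- as.vector(t(co$phased))
  ph <- co$phased
  pairs <- data.frame(iid = rownames(ph), hap1 = pmin(ph[, 1], ph[, 2]),
                      hap2 = pmax(ph[, 1], ph[, 2]), resolved = TRUE,
                      stringsAsFactors = FALSE)
  freqs <- haplotype_frequencies(pairs, co$phenotype)
  freqs$kept <- freqs$label %in% names(targets) # tag only the planted set
  sel <- select_tags(freqs, colnames(co$tag_alleles),
                     list(chrom = chrom, alleles = co$tag_alleles),
                     min_r2 = 0.7)
  sel$target <- unname(targets[sel$label])
  sel$correct <- sel$snp == co$tag_map[sel$label]
  # conditional sampling SD of realized r2, by replicate re-emission
  r2_reps <- vapply(seq_len(se_reps), function(r) {
    cor <- emit_tag_snps(co0, seed = seed + 7000L + r)
    vapply(names(targets), function(lab) {
      ld_stats(as.integer(chrom == lab),
               cor$tag_alleles[, cor$tag_map[lab]])["r2"]
    }, numeric(1))
  }, numeric(length(targets)))
  if (is.null(dim(r2_reps))) r2_reps <- matrix(r2_reps, nrow = 1)
  se <- apply(r2_reps, 1, stats::sd)
  sel$se <- se[match(sel$label, names(targets))]
  sel[, c("label", "target", "snp", "r2", "se", "tagged", "correct")]
}
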
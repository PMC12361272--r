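#' Simulate a case-control cohort under a logistic disease model
#'
#' Draws individuals by rejection sampling until both group quotas are
#' filled. Each raw draw receives two haplotypes i.i.d. from the pool,
#' Binomial(2, MAF) non-HLA dosages, sex ~ Bernoulli(0.5) and standard
#' normal principal components; the disease log-odds are
#' `intercept + sum(beta_h * dose_h) + gamma(pair) + sum(beta_snp * dose) +
#' covariate terms` and case status is Bernoulli(expit(eta)). Missing
#' non-HLA dosages are masked uniformly at `missing_rate`. The returned
#' cohort carries phased haplotype truth, an unphased HLA typing table
#' (two DQA1 + two DQB1 alleles per individual, phase discarded) and a
#' `truth` record with the config and realized frequencies.
#'
#' @param config A [sim_config()] object.
#' @param max_draws Abort with a diagnostic if quotas are not filled after
#'   this many raw draws (guards against near-zero acceptance probability).
#' @return Object of class `cohort`: list with elements `genotypes`
#'   ([geno_matrix()]), `phased` (n x 2 character matrix of haplotype
#'   labels, or NULL), `hla` (typing data.frame), `phenotype` (0/1 integer),
#'   `covariates` (data.frame `sex`, `PC1`, ...), `truth`.
#' @export
simulate_cohort <- function(config, max_draws = 5e6) {
  stop_if_not(inherits(config, "sim_config"), "config must be a sim_config")
  with_seed(config$seed, simulate_cohort_impl(config, max_draws))
}

simulate_cohort_impl <- function(config, max_draws) {
  n_cases <- config$n_cases; n_controls <- config$n_controls
  pool <- config$haplotype_pool
  snps <- config$nonhla_snps
  n_snp <- if (is.null(snps)) 0L else nrow(snps)
  n_pc <- length(config$pc_betas)
  gam <- config$interaction_effects

  kept <- list(); n_kept_cases <- 0L; n_kept_controls <- 0L
  total_draws <- 0L; total_cases_drawn <- 0L
  batch <- max(2L * (n_cases + n_controls), 2000L)

  while ((n_kept_cases < n_cases || n_kept_controls < n_controls) &&
         total_draws < max_draws) {
    B <- as.integer(min(batch, max_draws - total_draws))
    eta <- rep(config$intercept, B)

    if (!is.null(pool)) {
      h1 <- sample.int(nrow(pool), B, replace = TRUE, prob = pool$freq)
      h2 <- sample.int(nrow(pool), B, replace = TRUE, prob = pool$freq)
      eta <- eta + pool$beta[h1] + pool$beta[h2]
      if (length(gam)) {
        key <- pair_key(pool$label[h1], pool$label[h2])
        hit <- match(key, names(gam))
        eta <- eta + ifelse(is.na(hit), 0, gam[hit])
      }
    } else h1 <- h2 <- NULL

    if (n_snp) {
      G <- matrix(stats::rbinom(B * n_snp, 2L, rep(snps$maf, each = B)),
                  nrow = B, ncol = n_snp)
      eta <- eta + drop(G %*% snps$beta)
    } else G <- NULL

    sex <- stats::rbinom(B, 1L, 0.5)
    eta <- eta + config$sex_beta * sex
    if (n_pc) {
      PC <- matrix(stats::rnorm(B * n_pc), nrow = B, ncol = n_pc)
      eta <- eta + drop(PC %*% config$pc_betas)
    } else PC <- NULL

    y <- stats::rbinom(B, 1L, expit(eta))
    total_draws <- total_draws + B
    total_cases_drawn <- total_cases_drawn + sum(y)

    take <- (y == 1L & n_kept_cases + cumsum(y == 1L) <= n_cases) |
            (y == 0L & n_kept_controls + cumsum(y == 0L) <= n_controls)
    if (any(take)) {
      kept[[length(kept) + 1L]] <- list(
        y = y[take],
        h1 = if (is.null(h1)) NULL else h1[take],
        h2 = if (is.null(h2)) NULL else h2[take],
        G = if (is.null(G)) NULL else G[take, , drop = FALSE],
        sex = sex[take],
        PC = if (is.null(PC)) NULL else PC[take, , drop = FALSE])
      n_kept_cases <- n_kept_cases + sum(y[take] == 1L)
      n_kept_controls <- n_kept_controls + sum(y[take] == 0L)
    }
  }

  if (n_kept_cases < n_cases || n_kept_controls < n_controls) {
    stop(sprintf(paste0(
      "cohort quotas unreachable: after %d draws got %d/%d cases and %d/%d ",
      "controls (raw case rate %.4f); adjust intercept/effects or max_draws"),
      total_draws, n_kept_cases, n_cases, n_kept_controls, n_controls,
      total_cases_drawn / total_draws), call. = FALSE)
  }

  y <- unlist(lapply(kept, `[[`, "y"))
  sex <- unlist(lapply(kept, `[[`, "sex"))
  n <- length(y)
  iid <- sprintf("S%05d", seq_len(n))

  covariates <- data.frame(sex = sex)
  if (n_pc) {
    PC <- do.call(rbind, lapply(kept, `[[`, "PC"))
    colnames(PC) <- paste0("PC", seq_len(n_pc))
    covariates <- cbind(covariates, as.data.frame(PC))
  }
  rownames(covariates) <- iid

  genotypes <- NULL; snp_freq <- NULL
  if (n_snp) {
    G <- do.call(rbind, lapply(kept, `[[`, "G"))
    storage.mode(G) <- "double"
    if (config$missing_rate > 0) {
      G[stats::runif(length(G)) < config$missing_rate] <- NA_real_
    }
    dimnames(G) <- list(iid, snps$id)
    variants <- data.frame(id = snps$id, chr = as.character(snps$chr),
                           pos = snps$pos, a1 = "A", a2 = "G",
                           stringsAsFactors = FALSE)
    genotypes <- geno_matrix(G, variants)
    snp_freq <- colMeans(G, na.rm = TRUE) / 2
  }

  phased <- NULL; hla <- NULL; hap_freq <- NULL
  if (!is.null(pool)) {
    h1 <- pool$label[unlist(lapply(kept, `[[`, "h1"))]
    h2 <- pool$label[unlist(lapply(kept, `[[`, "h2"))]
    phased <- cbind(hap1 = h1, hap2 = h2)
    rownames(phased) <- iid
    a1 <- split_hap_label(h1); a2 <- split_hap_label(h2)
    # unphased typing: alleles sorted within locus, phase discarded
    dqa <- cbind(pmin(a1[, "dqa1"], a2[, "dqa1"]), pmax(a1[, "dqa1"], a2[, "dqa1"]))
    dqb <- cbind(pmin(a1[, "dqb1"], a2[, "dqb1"]), pmax(a1[, "dqb1"], a2[, "dqb1"]))
    hla <- data.frame(iid = iid, dqa1_1 = dqa[, 1], dqa1_2 = dqa[, 2],
                      dqb1_1 = dqb[, 1], dqb1_2 = dqb[, 2],
                      stringsAsFactors = FALSE)
    hap_freq <- table(factor(c(h1, h2), levels = pool$label)) / (2 * n)
    hap_freq <- stats::setNames(as.numeric(hap_freq), pool$label)
  }

  cohort <- list(
    genotypes = genotypes, phased = phased, hla = hla,
    phenotype = as.integer(y), covariates = covariates,
    truth = list(config = config, hap_freq = hap_freq, snp_freq = snp_freq,
                 n_draws = total_draws,
                 raw_case_rate = total_cases_drawn / total_draws,
                 acceptance_rate = n / total_draws),
    tag_alleles = NULL)
  class(cohort) <- "cohort"
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d cases / %d controls\n",
              sum(x$phenotype == 1L), sum(x$phenotype == 0L)))
  if (!is.null(x$genotypes))
    cat(sprintf("  %d variants (%s)\n", ncol(x$genotypes$dosage),
                paste(utils::head(x$genotypes$variants$id, 4), collapse = ", ")))
  if (!is.null(x$phased))
    cat(sprintf("  phased DQ haplotypes over %d labels\n",
                length(unique(as.vector(x$phased)))))
  invisible(x)
}

#' Expected phased r-squared between a haplotype and its tag allele
#'
#' Under symmetric per-chromosome flipping with error rate `eps`, a tag
#' allele equals the haplotype indicator with probability `1 - eps`. With
#' haplotype frequency `p` the tag allele frequency is
#' `q = p + eps * (1 - 2p)` and `r2 = p(1-p)(1-2 eps)^2 / (q(1-q))`,
#' which decreases monotonically from 1 (eps = 0) to 0 (eps = 1/2).
#'
#' @param eps Flip probability in [0, 0.5).
#' @param p Haplotype frequency in (0, 1).
#' @return Expected r-squared.
#' @export
tag_r2_given_epsilon <- function(eps, p) {
  q <- p + eps * (1 - 2 * p)
  p * (1 - p) * (1 - 2 * eps)^2 / (q * (1 - q))
}

#' Solve the flip rate that yields a target tag r-squared
#'
#' Inverts [tag_r2_given_epsilon()] by bisection on [0, 0.5).
#'
#' @param r2_target Target phased r-squared in (0, 1].
#' @param p Haplotype frequency in (0, 1).
#' @return Flip probability eps; exactly 0 when `r2_target == 1`.
#' @export
solve_tag_epsilon <- function(r2_target, p) {
  stop_if_not(r2_target > 0 && r2_target <= 1, "target r2 must be in (0, 1]")
  stop_if_not(p > 0 && p < 1, "haplotype frequency must be in (0, 1)")
  if (r2_target == 1) return(0)
  stats::uniroot(function(e) tag_r2_given_epsilon(e, p) - r2_target,
                 lower = 0, upper = 0.5 - 1e-9, tol = 1e-12)$root
}

#' Append LD-tagged SNP columns to a simulated cohort
#'
#' For each haplotype H with target r-squared, every chromosome carries the
#' tag allele `indicator(H)` flipped with probability eps, where eps is
#' solved by bisection so the expected phased r-squared equals the target
#' (eps = 0 for a perfect tag). Tag dosage per individual is the sum over
#' its two chromosomes. Phased tag alleles are retained in
#' `cohort$tag_alleles` (2n x k, chromosome-major) for phased LD
#' computation downstream.
#'
#' @param cohort A simulated [simulate_cohort()] cohort with phased truth.
#' @param tag_specs Named target r-squared vector (default: from the
#'   cohort's config).
#' @param seed Seed for the flip draws (default derived from the config
#'   seed).
#' @return The cohort with tag SNP columns appended to `genotypes`.
#' @export
emit_tag_snps <- function(cohort, tag_specs = cohort$truth$config$tag_specs,
                          seed = cohort$truth$config$seed + 1000L) {
  stop_if_not(!is.null(cohort$phased), "cohort has no phased haplotypes")
  if (!length(tag_specs)) return(cohort)
  stop_if_not(all(tag_specs > 0 & tag_specs <= 1), "target r2 must be in (0, 1]")
  chrom <- as.vector(t(cohort$phased)) # ind1 chr1, ind1 chr2, ind2 chr1, ...
  n2 <- length(chrom)
  with_seed(seed, {
    alleles <- matrix(0L, nrow = n2, ncol = length(tag_specs))
    for (k in seq_along(tag_specs)) {
      lab <- names(tag_specs)[k]
      p <- mean(chrom == lab)
      stop_if_not(p > 0 && p < 1,
                  "haplotype %s is monomorphic in the cohort; cannot tag", lab)
      eps <- solve_tag_epsilon(tag_specs[k], p)
      ind <- as.integer(chrom == lab)
      if (eps > 0) {
        flip <- stats::rbinom(n2, 1L, eps) == 1L
        ind[flip] <- 1L - ind[flip]
      }
      alleles[, k] <- ind
    }
    ids <- paste0("tag", seq_along(tag_specs), "_",
                  gsub("[^0-9A-Za-z]", "", names(tag_specs)))
    colnames(alleles) <- ids
    dosage <- alleles[seq(1, n2, by = 2), , drop = FALSE] +
              alleles[seq(2, n2, by = 2), , drop = FALSE]
    storage.mode(dosage) <- "double"
    rownames(dosage) <- rownames(cohort$phased)
    variants <- data.frame(id = ids, chr = "6",
                           pos = 32600000L + 1000L * seq_along(tag_specs),
                           a1 = "A", a2 = "G", stringsAsFactors = FALSE)
    cohort$genotypes <- if (is.null(cohort$genotypes))
      geno_matrix(dosage, variants)
    else append_variants(cohort$genotypes, dosage, variants)
    cohort$tag_alleles <- alleles
    cohort$tag_map <- stats::setNames(ids, names(tag_specs))
    cohort
  })
}
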
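#' Default DQA1-DQB1 haplotype pool
#'
#' A ten-haplotype reference pool for Chinese case-control simulations.
#' Frequencies are plausible East-Asian population values summing to one;
#' per-copy log-odds reflect the known direction of type 1 diabetes risk:
#' DR9 (`DQA1*03:02-DQB1*03:03`), DR4 (`DQA1*03:03-DQB1*04:01`) and DQ2
#' (`DQA1*05:01-DQB1*02:01`) confer risk, `DQA1*01:02-DQB1*06:02` (DR15) and
#' `DQA1*01:02-DQB1*05:02` are protective, and DQ8 (`DQA1*03:01-DQB1*03:02`)
#' is near-null as reported for Chinese cohorts. The pool contains one
#' ambiguous phasing quartet (`01:01/01:02 x 05:01/05:02`) so that two-locus
#' haplotype inference is exercised on double heterozygotes.
#'
#' @return data.frame with columns `label`, `freq`, `beta`.
#' @export
default_haplotype_pool <- function() {
  data.frame(
    label = c(
      "DQA1*03:02-DQB1*03:03", # DR9, common East-Asian risk
      "DQA1*03:03-DQB1*04:01", # DR4 subtype risk
      "DQA1*05:01-DQB1*02:01", # DQ2 risk
      "DQA1*01:02-DQB1*06:02", # DR15, strongly protective
      "DQA1*01:02-DQB1*05:02", # protective
      "DQA1*03:01-DQB1*03:02", # DQ8, near-null in Chinese data
      "DQA1*01:01-DQB1*05:01",
      "DQA1*06:01-DQB1*03:01",
      "DQA1*01:01-DQB1*05:02",
      "DQA1*01:02-DQB1*05:01"
    ),
    freq = c(0.16, 0.12, 0.08, 0.10, 0.12, 0.07, 0.12, 0.18, 0.03, 0.02),
    beta = c(1.0, 0.9, 1.2, -1.5, -0.8, 0.1, 0.0, 0.3, -0.4, -0.2),
    stringsAsFactors = FALSE
  )
}

default_interaction_effects <- function(pool = default_haplotype_pool()) {
  l <- pool$label
  effs <- c(0.8, 0.5, 0.6)
  names(effs) <- c(pair_key(l[1], l[3]), pair_key(l[1], l[1]), pair_key(l[2], l[3]))
  effs
}

#' Table of additive non-HLA susceptibility SNPs used by default
#'
#' Six representative markers with their published minor allele frequencies
#' and per-allele log-odds in Chinese type 1 diabetes case-control data,
#' used as the default additive SNP set of the simulator.
#'
#' @return data.frame with columns `id`, `chr`, `pos`, `maf`, `beta`.
#' @export
default_nonhla_snps <- function() {
  data.frame(
    id   = c("rs231770", "rs9274655", "rs10232170", "rs11256442", "rs689", "rs773125"),
    chr  = c("2", "6", "7", "10", "11", "12"),
    pos  = c(204729153L, 32636289L, 34181522L, 6079344L, 2182224L, 56394954L),
    maf  = c(0.322, 0.411, 0.280, 0.493, 0.035, 0.264),
    beta = c(0.273, 1.323, -0.391, -0.245, 1.031, 0.301),
    stringsAsFactors = FALSE
  )
}

#' Build and validate a cohort simulation configuration
#'
#' Defines the generating model of [simulate_cohort()]: a pool of DQA1-DQB1
#' haplotypes with per-copy log-odds, non-additive haplogenotype interaction
#' effects, target tag-SNP LD, additive non-HLA SNPs, covariate effects and
#' a logistic disease model. Defaults reproduce a discovery-style Chinese
#' type 1 diabetes case-control cohort (1303 cases / 2236 controls).
#'
#' @param n_cases,n_controls Group quotas (both > 0).
#' @param haplotype_pool data.frame (`label`, `freq`, `beta`) or NULL for a
#'   purely additive (no-HLA) model. Frequencies must sum to 1.
#' @param interaction_effects Named numeric vector of log-odds added when an
#'   individual carries the haplogenotype; names are canonical `"A|B"` keys
#'   (see [pair_key()]).
#' @param tag_specs Named numeric vector mapping haplotype label to target
#'   phased r-squared in (0, 1].
#' @param nonhla_snps data.frame (`id`, `chr`, `pos`, `maf`, `beta`) of
#'   additive SNPs; MAF in (0, 0.5].
#' @param sex_beta Log-odds for sex (coded 0/1).
#' @param pc_betas Numeric vector of per-principal-component log-odds;
#'   PCs are drawn standard normal.
#' @param intercept Baseline log-odds of disease among raw draws. Not a
#'   population prevalence estimate: case-control quotas are filled by
#'   rejection sampling.
#' @param missing_rate Probability that a non-HLA dosage entry is masked.
#' @param seed Integer seed; every draw of the simulator is a deterministic
#'   function of it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 1303L, n_controls = 2236L,
                       haplotype_pool = default_haplotype_pool(),
                       interaction_effects = if (is.null(haplotype_pool)) NULL
                         else default_interaction_effects(haplotype_pool),
                       tag_specs = if (is.null(haplotype_pool)) NULL else
                         stats::setNames(c(1.0, 0.9, 0.8, 0.95, 0.85),
                                         haplotype_pool$label[1:5]),
                       nonhla_snps = default_nonhla_snps(),
                       sex_beta = 0.15, pc_betas = c(0.3, -0.2),
                       intercept = -1.5, missing_rate = 0.02, seed = 1L) {
  stop_if_not(n_cases > 0 && n_controls > 0, "n_cases and n_controls must be positive")
  if (!is.null(haplotype_pool)) {
    stop_if_not(all(c("label", "freq", "beta") %in% names(haplotype_pool)),
                "haplotype_pool needs columns label, freq, beta")
    stop_if_not(abs(sum(haplotype_pool$freq) - 1) <= 1e-9,
                "haplotype frequencies must sum to 1 (got %.12f)", sum(haplotype_pool$freq))
    stop_if_not(all(haplotype_pool$freq >= 0), "haplotype frequencies must be >= 0")
    if (length(interaction_effects)) {
      labs <- unique(as.vector(split_pair_key(names(interaction_effects))))
      stop_if_not(all(labs %in% haplotype_pool$label),
                  "interaction_effects reference haplotypes absent from the pool")
    }
    if (length(tag_specs)) {
      stop_if_not(all(names(tag_specs) %in% haplotype_pool$label),
                  "tag_specs reference haplotypes absent from the pool")
      stop_if_not(all(tag_specs > 0 & tag_specs <= 1),
                  "tag r2 targets must lie in (0, 1]")
    }
  }
  if (!is.null(nonhla_snps) && nrow(nonhla_snps)) {
    stop_if_not(all(nonhla_snps$maf > 0 & nonhla_snps$maf <= 0.5),
                "SNP MAF must lie in (0, 0.5]")
    stop_if_not(!anyDuplicated(nonhla_snps$id), "duplicate SNP ids in nonhla_snps")
  }
  stop_if_not(missing_rate >= 0 && missing_rate < 1, "missing_rate must be in [0, 1)")
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    haplotype_pool = haplotype_pool,
    interaction_effects = interaction_effects,
    tag_specs = tag_specs,
    nonhla_snps = nonhla_snps,
    sex_beta = sex_beta, pc_betas = pc_betas,
    intercept = intercept, missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Cohort simulation config\n")
  cat(sprintf("  quotas: %d cases / %d controls\n", x$n_cases, x$n_controls))
  cat(sprintf("  haplotype pool: %s\n",
              if (is.null(x$haplotype_pool)) "none"
              else sprintf("%d haplotypes", nrow(x$haplotype_pool))))
  cat(sprintf("  interactions: %d; tag specs: %d; non-HLA SNPs: %d\n",
              length(x$interaction_effects), length(x$tag_specs),
              if (is.null(x$nonhla_snps)) 0L else nrow(x$nonhla_snps)))
  cat(sprintf("  intercept %.3f, missing rate %.3f, seed %d\n",
              x$intercept, x$missing_rate, x$seed))
  invisible(x)
}
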
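# Independent oracles and small fixtures. These deliberately avoid the
# package's own code paths: combinatorial formulas use choose(), AUC uses
# exhaustive pair counting.

# conditional exact HWE distribution by direct combinatorial counting:
# P(het = h | n, nA) = C(n, nAA) C(n - nAA, h) 2^h / C(2n, nA)
brute_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nA <- 2 * n_aa + n_ab
  nB <- 2 * n_bb + n_ab
  if (nA == 0 || nB == 0) return(1)
  nmin <- min(nA, nB)
  hets <- seq(nmin %% 2, nmin, by = 2)
  prob <- vapply(hets, function(h) {
    naa <- (nA - h) / 2
    choose(n, naa) * choose(n - naa, h) * 2^h
  }, numeric(1))
  prob <- prob / sum(prob)
  obs <- prob[hets == n_ab]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# AUC by exhaustive concordant-pair counting, ties worth 1/2
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# direct 2x2 LD formulas from haplotype counts (independent arithmetic)
brute_ld <- function(n11, n10, n01, n00) {
  n <- n11 + n10 + n01 + n00
  p11 <- n11 / n
  pA <- (n11 + n10) / n
  pB <- (n11 + n01) / n
  D <- p11 - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  c(r2 = r2, dprime = if (D == 0) 0 else D / dmax)
}

# expand LD haplotype counts into chromosome vectors
ld_vectors <- function(n11, n10, n01, n00) {
  list(x = rep(c(1, 1, 0, 0), c(n11, n10, n01, n00)),
       y = rep(c(1, 0, 1, 0), c(n11, n10, n01, n00)))
}

# small three-haplotype pool for toy tests
toy_pool <- function() {
  data.frame(label = c("DQA1*01:01-DQB1*02:01", "DQA1*02:01-DQB1*03:01",
                       "DQA1*03:01-DQB1*04:01"),
             freq = c(0.5, 0.3, 0.2), beta = c(0.8, 0, -0.5),
             stringsAsFactors = FALSE)
}

# resolved haplotype-pair table from two label vectors
make_pairs <- function(h1, h2, iid = sprintf("I%03d", seq_along(h1))) {
  data.frame(iid = iid, hap1 = pmin(h1, h2), hap2 = pmax(h1, h2),
             resolved = TRUE, stringsAsFactors = FALSE)
}

# random additive-only score model over named SNPs
random_model <- function(n_dq = 3, n_ho = 4, n_nh = 5, n_inter = 2,
                         labels = paste0("DQA1*0", 1:5, ":01-DQB1*06:0", 1:5)) {
  dq <- stats::setNames(stats::rnorm(n_dq), sample(labels, n_dq))
  inter_pairs <- replicate(n_inter, sample(names(dq), 2, replace = TRUE))
  inter <- stats::setNames(stats::rnorm(n_inter),
                           pair_key(inter_pairs[1, ], inter_pairs[2, ]))
  inter <- inter[!duplicated(names(inter))]
  ho <- stats::setNames(stats::rnorm(n_ho), paste0("hla", seq_len(n_ho)))
  nh <- stats::setNames(stats::rnorm(n_nh), paste0("snp", seq_len(n_nh)))
  m <- build_model()
  m$dq_additive <- dq; m$dq_interactions <- inter
  m$hla_other <- ho; m$non_hla <- nh
  m$effect_alleles <- stats::setNames(rep("A", n_ho + n_nh), c(names(ho), names(nh)))
  m
}
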
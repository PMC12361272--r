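#' Infer DQA1-DQB1 haplotype pairs from unphased typing
#'
#' For each individual, at most two phasings are consistent with the
#' unphased DQA1 and DQB1 allele pairs; the phasing maximizing the product
#' of reference pool frequencies is chosen (the two-locus special case of
#' an EM M-step). Ties are broken lexicographically by label and reported.
#' Individuals whose consistent phasings all contain zero-frequency
#' haplotypes, or who carry alleles absent from the pool, are flagged
#' unresolved.
#'
#' @param typing data.frame with columns `iid`, `dqa1_1`, `dqa1_2`,
#'   `dqb1_1`, `dqb1_2` (four-digit allele strings such as `"03:03"`).
#' @param pool_freq Named numeric vector of reference haplotype
#'   frequencies, names in `"DQA1*xx:xx-DQB1*yy:yy"` form.
#' @return data.frame `iid`, `hap1`, `hap2` (canonical: `hap1 <= hap2`),
#'   `resolved`, `ambiguous` (both phasings possible), `tied`,
#'   `lik_ratio` (chosen vs alternative frequency product).
#' @export
infer_haplogenotypes <- function(typing, pool_freq) {
  need <- c("iid", "dqa1_1", "dqa1_2", "dqb1_1", "dqb1_2")
  stop_if_not(all(need %in% names(typing)), "typing must have columns %s",
              paste(need, collapse = ", "))
  f <- function(lab) {
    v <- pool_freq[lab]
    ifelse(is.na(v), 0, v)
  }
  n <- nrow(typing)
  hap1 <- hap2 <- rep(NA_character_, n)
  resolved <- ambiguous <- tied <- logical(n)
  lik_ratio <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- c(typing$dqa1_1[i], typing$dqa1_2[i])
    b <- c(typing$dqb1_1[i], typing$dqb1_2[i])
    # phasing 1: a1-b1 / a2-b2 ; phasing 2: a1-b2 / a2-b1
    p1 <- c(make_hap_label(a[1], b[1]), make_hap_label(a[2], b[2]))
    p2 <- c(make_hap_label(a[1], b[2]), make_hap_label(a[2], b[1]))
    w1 <- f(p1[1]) * f(p1[2])
    w2 <- f(p2[1]) * f(p2[2])
    same <- setequal(p1, p2)
    if (w1 == 0 && w2 == 0) next # unresolvable
    if (same) { choice <- p1 }
    else if (w1 > w2) choice <- p1
    else if (w2 > w1) choice <- p2
    else { # tie between distinct phasings: lexicographic by sorted labels
      tied[i] <- TRUE
      s1 <- sort(p1); s2 <- sort(p2)
      choice <- if (paste(s1, collapse = "|") <= paste(s2, collapse = "|")) p1 else p2
    }
    ambiguous[i] <- !same && w1 > 0 && w2 > 0
    lik_ratio[i] <- if (same || min(w1, w2) == 0) Inf else max(w1, w2) / min(w1, w2)
    ch <- sort(choice)
    hap1[i] <- ch[1]; hap2[i] <- ch[2]
    resolved[i] <- TRUE
  }
  if (any(tied))
    message(sprintf("%d individual(s) had tied phasings; lexicographic tie-break applied",
                    sum(tied)))
  data.frame(iid = typing$iid, hap1 = hap1, hap2 = hap2, resolved = resolved,
             ambiguous = ambiguous, tied = tied, lik_ratio = lik_ratio,
             stringsAsFactors = FALSE)
}

#' Case/control haplotype frequencies with the 0.5% filter
#'
#' Chromosome-level frequencies of each haplotype per phenotype group over
#' resolved individuals. A haplotype is kept iff its frequency exceeds
#' `min_freq` (default 0.005) in cases AND in controls.
#'
#' @param pairs [infer_haplogenotypes()] output (or any data.frame with
#'   `hap1`, `hap2`, `resolved`).
#' @param phenotype 0/1 vector aligned to `pairs`.
#' @param min_freq Frequency threshold (exclusive).
#' @return data.frame of class `dq_freqs`: `label`, `freq_cases`,
#'   `freq_controls`, `kept`.
#' @export
haplotype_frequencies <- function(pairs, phenotype, min_freq = 0.005) {
  stop_if_not(nrow(pairs) == length(phenotype), "phenotype not aligned to pairs")
  ok <- pairs$resolved
  labs <- sort(unique(c(pairs$hap1[ok], pairs$hap2[ok])))
  count_group <- function(g) {
    idx <- ok & phenotype == g
    tab <- table(factor(c(pairs$hap1[idx], pairs$hap2[idx]), levels = labs))
    as.numeric(tab) / max(1L, 2L * sum(idx))
  }
  out <- data.frame(label = labs, freq_cases = count_group(1L),
                    freq_controls = count_group(0L), stringsAsFactors = FALSE)
  out$kept <- out$freq_cases > min_freq & out$freq_controls > min_freq
  class(out) <- c("dq_freqs", class(out))
  out
}

#' Linkage disequilibrium r-squared and D-prime from phased chromosomes
#'
#' From the phased 2x2 haplotype table of two binary markers:
#' `D = p11 - pA pB`, `r2 = D^2 / (pA(1-pA) pB(1-pB))`, and Lewontin's
#' `D' = D / Dmax` with `Dmax = min(pA(1-pB), (1-pA)pB)` for `D > 0` and
#' `min(pA pB, (1-pA)(1-pB))` for `D < 0`; `D = 0` gives `D' = 0`.
#'
#' @param x,y Equal-length binary (0/1) vectors, one entry per chromosome;
#'   both must be polymorphic.
#' @return Named numeric vector `c(r2, dprime)`.
#' @export
ld_stats <- function(x, y) {
  stop_if_not(length(x) == length(y), "chromosome vectors differ in length")
  x <- as.numeric(x); y <- as.numeric(y)
  stop_if_not(all(x %in% c(0, 1)) && all(y %in% c(0, 1)),
              "inputs must be binary 0/1 per chromosome")
  pA <- mean(x); pB <- mean(y)
  stop_if_not(pA > 0 && pA < 1 && pB > 0 && pB < 1, "monomorphic input")
  p11 <- mean(x == 1 & y == 1)
  D <- p11 - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dprime <- if (D > 0) D / min(pA * (1 - pB), (1 - pA) * pB)
            else if (D < 0) D / min(pA * pB, (1 - pA) * (1 - pB))
            else 0
  c(r2 = r2, dprime = dprime)
}

#' Select the best tag SNP per haplotype by r-squared and D-prime
#'
#' For each kept haplotype, picks the candidate SNP maximizing r-squared;
#' ties are broken by larger |D'|, then smaller genomic position. When
#' phased chromosome data are available LD is computed on phased alleles;
#' otherwise it falls back to the squared Pearson correlation of expected
#' dosages (D' unavailable, method flagged `"dosage"`). Haplotypes whose
#' best candidate falls below `min_r2` are reported untagged rather than
#' silently omitted.
#'
#' @param freqs [haplotype_frequencies()] table (only `kept` rows are
#'   tagged).
#' @param candidates Character vector of candidate SNP ids.
#' @param hap_data Either a list `list(chrom = <2n labels>, alleles = <2n x
#'   m 0/1 matrix>)` for phased mode, or `list(hap_doses = <n x k>, snp_doses
#'   = <n x m>)` for the dosage fallback.
#' @param positions Optional named positions for tie-breaking.
#' @param min_r2 Acceptance threshold (default 0.7).
#' @return data.frame of class `tag_assignment`: `label snp r2 dprime
#'   tagged method`.
#' @export
select_tags <- function(freqs, candidates, hap_data, positions = NULL,
                        min_r2 = 0.7) {
  stop_if_not(length(candidates) > 0, "no candidate SNPs supplied")
  phased <- !is.null(hap_data$chrom)
  labs <- freqs$label[freqs$kept]
  rows <- lapply(labs, function(lab) {
    r2 <- dp <- rep(NA_real_, length(candidates))
    for (k in seq_along(candidates)) {
      snp <- candidates[k]
      if (phased) {
        ind <- as.numeric(hap_data$chrom == lab)
        al <- hap_data$alleles[, snp]
        if (length(unique(al)) < 2L || length(unique(ind)) < 2L) next
        st <- ld_stats(ind, al)
        r2[k] <- st["r2"]; dp[k] <- st["dprime"]
      } else {
        hd <- hap_data$hap_doses[, lab]
        sd_ <- hap_data$snp_doses[, snp]
        ok <- !is.na(hd) & !is.na(sd_)
        if (stats::sd(hd[ok]) == 0 || stats::sd(sd_[ok]) == 0) next
        r2[k] <- stats::cor(hd[ok], sd_[ok])^2
      }
    }
    if (all(is.na(r2)))
      return(data.frame(label = lab, snp = NA_character_, r2 = NA_real_,
                        dprime = NA_real_, tagged = FALSE,
                        stringsAsFactors = FALSE))
    pos <- if (is.null(positions)) seq_along(candidates)
           else positions[candidates]
    ord <- order(-r2, -abs(dp), pos, na.last = TRUE)
    b <- ord[1]
    data.frame(label = lab, snp = candidates[b], r2 = r2[b], dprime = dp[b],
               tagged = !is.na(r2[b]) && r2[b] >= min_r2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "method") <- if (phased) "phased" else "dosage"
  attr(out, "min_r2") <- min_r2
  class(out) <- c("tag_assignment", class(out))
  out
}

#' Per-individual haplotype dosage matrix
#'
#' Dose of haplotype H = number of copies carried (0, 1 or 2). Unresolved
#' individuals produce missing rows, counted in attribute `n_unresolved`.
#'
#' @param pairs [infer_haplogenotypes()] output.
#' @param labels Haplotype labels forming the columns (default: all labels
#'   observed among resolved pairs).
#' @return n x k numeric matrix; row sums are 2 for every resolved
#'   individual when `labels` covers all carried haplotypes.
#' @export
haplotype_dosages <- function(pairs, labels = NULL) {
  ok <- pairs$resolved
  if (is.null(labels)) labels <- sort(unique(c(pairs$hap1[ok], pairs$hap2[ok])))
  M <- matrix(NA_real_, nrow = nrow(pairs), ncol = length(labels),
              dimnames = list(pairs$iid, labels))
  M[ok, ] <- 0
  for (j in seq_along(labels)) {
    M[ok, j] <- (pairs$hap1[ok] == labels[j]) + (pairs$hap2[ok] == labels[j])
  }
  attr(M, "n_unresolved") <- sum(!ok)
  M
}
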
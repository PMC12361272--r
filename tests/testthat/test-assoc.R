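test_that("HWE exact test matches brute-force enumeration and its symmetries", {
  # monomorphic: p = 1
  expect_identical(hwe_exact_test(0, 0, 50), 1)
  expect_identical(hwe_exact_test(50, 0, 0), 1)
  # hand case from full enumeration over het counts {0,2,...,10}
  expect_equal(hwe_exact_test(3, 4, 3), brute_hwe(3, 4, 3), tolerance = 1e-12)
  # label symmetry and random-table agreement
  set.seed(42)
  for (i in 1:40) {
    n <- sample(5:80, 1)
    nA <- sample(1:(2 * n - 1), 1)
    nmin <- min(nA, 2 * n - nA)
    h <- sample(seq(nmin %% 2, nmin, by = 2), 1)
    naa <- (nA - h) / 2; nbb <- n - naa - h
    expect_equal(hwe_exact_test(naa, h, nbb), brute_hwe(naa, h, nbb),
                 tolerance = 1e-10)
    expect_equal(hwe_exact_test(naa, h, nbb), hwe_exact_test(nbb, h, naa),
                 tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

test_that("snp_qc flags monomorphic, low-MAF, HWE-failing and missing-heavy variants", {
  set.seed(1)
  n <- 200
  D <- cbind(
    mono = rep(0, n),
    ok = rbinom(n, 2, 0.3),
    lowmaf = rbinom(n, 2, 0.02),
    hwe = rep(c(0, 2), each = n / 2),       # no heterozygotes at p ~ 0.5
    missing = ifelse(runif(n) < 0.06, NA, rbinom(n, 2, 0.3)))
  v <- data.frame(id = colnames(D), chr = "1", pos = 1:5, a1 = "A", a2 = "G",
                  stringsAsFactors = FALSE)
  g <- geno_matrix(D, v)
  qc <- snp_qc(g, miss_max = 0.05)
  expect_identical(qc$reasons[qc$id == "mono"], "monomorphic")
  expect_true(qc$kept[qc$id == "ok"])
  expect_identical(qc$reasons[qc$id == "lowmaf"], "low_maf")
  expect_match(qc$reasons[qc$id == "hwe"], "hwe_fail")
  # exact-test oracle: AA=100, Aa=0, aa=100 is far below 1e-4
  expect_lt(brute_hwe(100, 0, 100), 1e-4)
  expect_match(qc$reasons[qc$id == "missing"], "high_missing")
  # kept iff reasons empty
  expect_identical(qc$kept, qc$reasons == "")
})

test_that("QC with thresholds disabled is the identity and never adds variants", {
  cfg <- sim_config(n_cases = 150, n_controls = 150, seed = 8)
  co <- simulate_cohort(cfg)
  qc_off <- snp_qc(co$genotypes, maf_min = 0, hwe_p = 0, miss_max = 1,
                   drop_monomorphic = FALSE)
  expect_true(all(qc_off$kept))
  qc_on <- snp_qc(co$genotypes, phenotype = co$phenotype)
  expect_lte(sum(qc_on$kept), nrow(co$genotypes$variants))
  # HWE in controls only: control-stratum test differs from all-sample test
  expect_identical(nrow(qc_on), ncol(co$genotypes$dosage))
})

test_that("logistic fit matches the 2x2 closed form for a 0/2-coded predictor", {
  # table: cases (30 exposed, 20 unexposed), controls (10, 40)
  y <- rep(c(1, 0), c(50, 50))
  x <- c(rep(2, 30), rep(0, 20), rep(2, 10), rep(0, 40))
  fit <- fit_logistic(y, matrix(x, ncol = 1, dimnames = list(NULL, "dose")))
  or_table <- (30 * 40) / (20 * 10)
  expect_equal(fit$beta[2], log(or_table) / 2, tolerance = 1e-6)
  # OR/CI identities downstream
  g <- geno_matrix(matrix(x, ncol = 1, dimnames = list(NULL, "rs1")),
                   data.frame(id = "rs1", chr = "1", pos = 1L, a1 = "A",
                              a2 = "G", stringsAsFactors = FALSE))
  res <- run_gwas(g, y)
  expect_equal(res$or, exp(res$beta), tolerance = 1e-12)
  expect_equal(res$ci_low, exp(res$beta - 1.96 * res$se), tolerance = 1e-12)
  expect_equal(res$ci_high, exp(res$beta + 1.96 * res$se), tolerance = 1e-12)
})

test_that("perfect separation is flagged, never silently estimated", {
  y <- rep(c(1, 0), each = 30)
  x <- ifelse(y == 1, 2, 0)
  fit <- fit_logistic(y, matrix(x, ncol = 1))
  expect_true(attr(fit, "flagged"))
  expect_true(all(is.na(fit$beta)))
  expect_match(attr(fit, "diagnostic"), "separation|converge")
})

test_that("aliased columns get NA estimates without disturbing the rest", {
  set.seed(2)
  x <- rbinom(200, 2, 0.4)
  y <- rbinom(200, 1, plogis(-0.3 + 0.5 * x))
  f1 <- fit_logistic(y, cbind(dose = x))
  f2 <- fit_logistic(y, cbind(dose = x, zero = 0))
  expect_false(attr(f2, "flagged"))
  expect_true(is.na(f2$beta[f2$term == "zero"]))
  expect_equal(f2$beta[f2$term == "dose"], f1$beta[f1$term == "dose"],
               tolerance = 1e-10)
})

test_that("covariate screening keeps informative covariates and drops degenerate ones", {
  set.seed(11)
  n <- 2000
  y <- rep(c(1, 0), each = n / 2)
  hits <- 0
  for (r in 1:30) {
    covs <- data.frame(
      const = 1,                               # constant: never selected
      noise = rnorm(n),                        # null covariate
      pc_shift = rnorm(n, mean = ifelse(y == 1, 1, 0))) # planted 1-SD shift
    sel <- screen_covariates(y, covs)
    expect_false("const" %in% sel)
    hits <- hits + ("pc_shift" %in% sel)
  }
  expect_equal(hits, 30) # ~100% power at this shift and n
  # covariate equal to y: separation-flagged, excluded with warning
  expect_warning(sel2 <- screen_covariates(y, data.frame(leak = y)),
                 "excluded")
  expect_false("leak" %in% sel2)
})

test_that("gwas rows are deterministic per variant and handle duplicates/missingness", {
  cfg <- sim_config(n_cases = 300, n_controls = 300, seed = 13,
                    tag_specs = NULL, missing_rate = 0.05)
  co <- simulate_cohort(cfg)
  D <- co$genotypes$dosage
  D2 <- cbind(D, dup = D[, "rs689"])
  v2 <- rbind(co$genotypes$variants,
              within(co$genotypes$variants[co$genotypes$variants$id == "rs689", ],
                     id <- "dup"))
  g2 <- geno_matrix(D2, v2)
  res <- run_gwas(g2, co$phenotype)
  a <- res[res$id == "rs689", -1]; b <- res[res$id == "dup", -1]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  expect_true(all(is.finite(res$beta))) # mean imputation handled missing
})

test_that("genomic inflation has its closed-form anchors and null behaviour", {
  expect_equal(genomic_inflation(rep(0.5, 11)), 1.0, tolerance = 1e-12)
  # halving every chi-squared statistic halves lambda
  set.seed(3)
  chi <- rchisq(2001, df = 1)
  p1 <- pchisq(chi, 1, lower.tail = FALSE)
  p2 <- pchisq(chi / 2, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p2), genomic_inflation(p1) / 2,
               tolerance = 1e-9)
  # uniform p-values are the null: lambda ~ 1
  set.seed(4)
  expect_true(abs(genomic_inflation(runif(1e5)) - 1) < 0.05)
  expect_error(genomic_inflation(numeric(0)), "p-values")
})

test_that("fixed-effect meta-analysis obeys its closed forms", {
  mk <- function(beta, se) {
    data.frame(id = "rs1", a1 = "A", a2 = "G", beta = beta, se = se,
               stringsAsFactors = FALSE)
  }
  # identical cohorts: beta unchanged, SE / sqrt(2); variance halved exactly
  m <- meta_fixed(list(mk(0.4, 0.1), mk(0.4, 0.1)))
  expect_equal(m$beta, 0.4, tolerance = 1e-12)
  expect_equal(m$se, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(m$se^2, 0.1^2 / 2, tolerance = 1e-15)
  # SE -> infinity: pooled result equals the informative cohort
  m2 <- meta_fixed(list(mk(0.4, 0.1), mk(-3, 1e9)))
  expect_equal(m2$beta, 0.4, tolerance = 1e-6)
  expect_equal(m2$se, 0.1, tolerance = 1e-6)
  # three cohorts, hand-computed weighted mean
  b <- c(0.2, 0.5, -0.1); s <- c(0.1, 0.2, 0.15)
  w <- 1 / s^2
  m3 <- meta_fixed(list(mk(b[1], s[1]), mk(b[2], s[2]), mk(b[3], s[3])))
  expect_equal(m3$beta, sum(w * b) / sum(w), tolerance = 1e-12)
  expect_equal(m3$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  expect_lte(m3$se, min(s))
  # allele swap flips the sign; incompatible alleles abort
  swapped <- mk(-0.4, 0.1); swapped$a1 <- "G"; swapped$a2 <- "A"
  m4 <- meta_fixed(list(mk(0.4, 0.1), swapped))
  expect_equal(m4$beta, 0.4, tolerance = 1e-12)
  bad <- mk(0.4, 0.1); bad$a1 <- "T"
  expect_error(meta_fixed(list(mk(0.4, 0.1), bad)), "allele mismatch")
})
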
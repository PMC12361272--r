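test_that("AUC equals exhaustive pair counting, with ties worth one half", {
  # perfect separation
  expect_equal(roc_auc(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0))$auc, 1)
  # 5 cases / 5 controls, hand-listed scores with ties
  s <- c(3.1, 2.0, 2.0, 4.5, 0.7, 1.9, 2.0, 0.7, 3.0, 1.1)
  l <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  expect_equal(roc_auc(s, l)$auc, brute_auc(s, l), tolerance = 1e-12)
  # random instances, discrete scores to force ties
  set.seed(19)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    l <- c(1, 0, rbinom(n - 2, 1, 0.4))
    s <- sample(1:8, n, replace = TRUE)
    expect_equal(roc_auc(s, l)$auc, brute_auc(s, l), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "case and one control")
})

test_that("the ROC curve has its endpoints and monotone operating points", {
  set.seed(31)
  s <- rnorm(200); l <- rbinom(200, 1, 0.5)
  rc <- roc_auc(s, l)
  fpr <- 1 - rc$specificity
  expect_equal(c(fpr[1], rc$sensitivity[1]), c(0, 0))
  expect_equal(c(fpr[length(fpr)], rc$sensitivity[length(fpr)]), c(1, 1))
  expect_true(all(diff(rc$sensitivity) >= 0))
  expect_true(all(diff(fpr) >= 0))
  expect_true(rc$auc >= 0 && rc$auc <= 1)
})

test_that("AUC is invariant under strictly monotone transforms and matches pROC", {
  set.seed(23)
  s <- rnorm(300); l <- rbinom(300, 1, 0.4)
  a <- roc_auc(s, l)$auc
  expect_equal(roc_auc(exp(s), l)$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(rank(s), l)$auc, a, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  pr <- pROC::roc(l, s, quiet = TRUE, direction = "<")
  expect_equal(a, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("shuffled labels give a null AUC near one half", {
  set.seed(41)
  s <- rnorm(2000)
  l <- sample(rep(c(1, 0), each = 1000))
  a <- roc_auc(s, l)$auc
  se <- sqrt(grskit:::delong_auc_var(s, l))
  expect_lt(abs(a - 0.5), 3 * se)
})

test_that("average precision matches hand-stepped sums and its anchors", {
  # perfect separation
  expect_equal(pr_auc(c(9, 8, 1, 2), c(1, 1, 0, 0)), 1)
  # toy 4-point hand computation:
  # thresholds desc 4,3,2,1 -> precision 1, 1/2, 2/3, 3/4 at recalls
  # 1/3, 1/3, 2/3, 1 -> AP = 1/3 * (1 + 2/3 + 3/4)
  s <- c(4, 3, 2, 1); l <- c(1, 0, 1, 1)
  expect_equal(pr_auc(s, l), 1 / 3 + (1 / 3) * (2 / 3) + (1 / 3) * (3 / 4),
               tolerance = 1e-12)
  # uninformative scores: PRAUC ~ prevalence
  set.seed(3)
  s <- rnorm(4000); l <- rbinom(4000, 1, 0.3)
  expect_lt(abs(pr_auc(s, l) - mean(l)), 0.05)
})

test_that("paired DeLong has its degenerate anchors and agrees with pROC", {
  set.seed(13)
  l <- rbinom(400, 1, 0.5)
  a <- rnorm(400) + l
  # identical and rank-identical scores: z = 0, p = 1
  r <- delong_paired(a, a, l)
  expect_equal(r$z, 0); expect_equal(r$p, 1)
  r2 <- delong_paired(a, plogis(a), l)
  expect_equal(r2$p, 1)
  # cross-check the full statistic against pROC on correlated scores
  skip_if_not_installed("pROC")
  b <- a + rnorm(400, sd = 1.5)
  ours <- delong_paired(a, b, l)
  ref <- pROC::roc.test(pROC::roc(l, a, quiet = TRUE, direction = "<"),
                        pROC::roc(l, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ours$z, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
})

test_that("unpaired DeLong is antisymmetric and agrees with pROC", {
  set.seed(17)
  l1 <- rbinom(300, 1, 0.5); s1 <- rnorm(300) + 1.2 * l1
  l2 <- rbinom(250, 1, 0.4); s2 <- rnorm(250) + 0.4 * l2
  r12 <- delong_unpaired(s1, l1, s2, l2)
  r21 <- delong_unpaired(s2, l2, s1, l1)
  expect_equal(r12$z, -r21$z, tolerance = 1e-12)
  expect_equal(r12$p, r21$p, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(l1, s1, quiet = TRUE, direction = "<"),
                        pROC::roc(l2, s2, quiet = TRUE, direction = "<"),
                        method = "delong", paired = FALSE)
  # pROC reports the same statistic but a t-tail; we use the normal tail
  expect_equal(r12$z, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(r12$p, 2 * pnorm(-abs(unname(ref$statistic))), tolerance = 1e-8)
  # one stratum perfectly separated, the other uninformative at large n
  l3 <- rep(c(1, 0), each = 300)
  r3 <- delong_unpaired(l3 + 0, l3, rnorm(600), rep(c(1, 0), 300))
  expect_lt(r3$p, 1e-6)
})

test_that("DeLong variance of the AUC difference matches the bootstrap", {
  set.seed(71)
  n <- 400
  l <- rbinom(n, 1, 0.5)
  a <- rnorm(n) + 0.9 * l
  b <- 0.6 * a + rnorm(n, sd = 1)
  ours <- delong_paired(a, b, l)$var_diff
  boot <- replicate(2000, {
    i <- sample.int(n, replace = TRUE)
    if (length(unique(l[i])) < 2) return(NA_real_)
    roc_auc(a[i], l[i])$auc - roc_auc(b[i], l[i])$auc
  })
  expect_lt(abs(ours - var(boot, na.rm = TRUE)) / var(boot, na.rm = TRUE), 0.15)
})

test_that("cutoff thresholds sit at the requested control centiles", {
  set.seed(91)
  neg <- rnorm(400); pos <- rnorm(300, mean = 1.5)
  scores <- c(pos, neg); labels <- rep(c(1, 0), c(300, 400))
  ct <- cutoff_table(scores, labels, specificity_grid = c(0.90, 0.95, 0.99))
  expect_equal(ct$threshold[ct$specificity_requested == 0.95],
               unname(quantile(neg, 0.95, type = 7)), tolerance = 1e-12)
  expect_equal(ct$centile_neg[ct$specificity_requested == 0.95], 95,
               tolerance = 0.5)
  # monotonicity: as the threshold rises sensitivity falls, specificity rises
  expect_true(all(diff(ct$threshold) > 0))
  expect_true(all(diff(ct$sensitivity) <= 0))
  expect_true(all(diff(ct$specificity) >= 0))
  # hand-computed sensitivity on a small fixture
  neg2 <- 1:20; pos2 <- c(5, 12, 18, 19, 25)
  ct2 <- cutoff_table(c(pos2, neg2), rep(c(1, 0), c(5, 20)),
                      specificity_grid = 0.95)
  thr <- unname(quantile(neg2, 0.95, type = 7)) # 19.05
  expect_equal(ct2$threshold, thr, tolerance = 1e-12)
  expect_equal(ct2$sensitivity, mean(pos2 > thr)) # only 25 exceeds it
  # exchangeable null at specificity 0.5: sensitivity ~ 0.5
  set.seed(92)
  s <- rnorm(4000); l <- rep(c(1, 0), 2000)
  ct3 <- cutoff_table(s, l, specificity_grid = 0.5)
  expect_lt(abs(ct3$sensitivity - 0.5), 0.05)
  # dual-direction rule: low cutoff with specificity against the cases
  ct4 <- cutoff_table(scores, labels, specificity_grid = 0.95,
                      direction = "less")
  expect_equal(ct4$threshold, unname(quantile(pos, 0.05, type = 7)),
               tolerance = 1e-12)
  expect_gte(ct4$specificity, 0.95 - 1e-9)
  expect_error(cutoff_table(scores, labels, specificity_grid = 1.2), "\\(0, 1\\)")
})

test_that("tertiles split nine distinct values into three groups of three", {
  t <- tertiles(c(10, 20, 30, 40, 50, 60, 70, 80, 90))
  expect_identical(as.vector(table(t)), c(3L, 3L, 3L))
  expect_identical(levels(t), c("low", "mid", "high"))
})

test_that("group comparisons detect real shifts and respect the null", {
  set.seed(61)
  # power: 1-SD shift at n = 200/200 detected essentially always
  hits <- 0
  for (r in 1:30) {
    v <- c(rnorm(200), rnorm(200, 1))
    g <- rep(c("a", "b"), each = 200)
    hits <- hits + (stratify_and_compare(v, g)$p < 0.05)
  }
  expect_gte(hits, 29)
  # type I: identical groups reject at close to the nominal rate
  rej <- 0
  for (r in 1:400) {
    v <- rnorm(120)
    g <- rep(c("a", "b"), 60)
    rej <- rej + (stratify_and_compare(v, g)$p < 0.05)
  }
  expect_lte(rej / 400, 0.08)
  # >2 groups use ANOVA / Kruskal-Wallis
  v <- rnorm(90); g <- rep(c("a", "b", "c"), 30)
  expect_match(stratify_and_compare(v, g, mode = "parametric")$method, "ANOVA")
  expect_match(stratify_and_compare(v, g)$method, "Kruskal")
  expect_error(stratify_and_compare(v, rep("a", 90)), "two")
})

test_that("score discrimination grows with the generating effect sizes", {
  aucs <- vapply(c(0.5, 1, 1.5), function(scale) {
    pool <- default_haplotype_pool()
    pool$beta <- pool$beta * scale
    cfg <- sim_config(n_cases = 700, n_controls = 700, haplotype_pool = pool,
                      interaction_effects = NULL, tag_specs = NULL,
                      nonhla_snps = NULL, seed = 303)
    co <- simulate_cohort(cfg)
    m <- build_model()
    m$dq_additive <- stats::setNames(pool$beta, pool$label)
    sc <- score_cohort(m, cohort = co)
    roc_auc(sc$total, co$phenotype)$auc
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})
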
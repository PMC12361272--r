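test_that("model assembly takes ln(OR) weights and applies retention thresholds", {
  dq <- data.frame(label = c("DQA1*01:01-DQB1*02:01", "DQA1*02:01-DQB1*03:01"),
                   or = c(2.804, 1.0), p = c(1e-10, 0.9),
                   stringsAsFactors = FALSE)
  dq$beta <- NULL
  ho <- data.frame(id = c("h1", "h2"), a1 = "A", or = c(1.8, 1.5),
                   p = c(1e-5, 1e-3), stringsAsFactors = FALSE)
  nh <- data.frame(id = c("s1", "s2"), a1 = "G", or = c(1.4, 1.3),
                   p = c(1e-9, 1e-7), stringsAsFactors = FALSE)
  m <- build_model(dq_assoc = dq, hla_other_assoc = ho, non_hla_assoc = nh)
  expect_equal(unname(m$dq_additive[1]), log(2.804), tolerance = 1e-12)
  # OR = 1 gives weight exactly 0; DQ additive terms are not p-filtered
  expect_identical(unname(m$dq_additive[2]), 0)
  # HLA threshold 4.72e-4: h2 at 1e-3 excluded
  expect_identical(names(m$hla_other), "h1")
  # non-HLA threshold 5e-8: s2 at 1e-7 excluded
  expect_identical(names(m$non_hla), "s1")
  bad <- nh; bad$or <- c(-1, 1.3)
  expect_error(build_model(non_hla_assoc = bad, nonhla_p = 1), "OR")
})

test_that("scoring identities: empty model, hand sums, lookup precedence", {
  empty <- build_model()
  expect_identical(score_individual(empty)$total, 0)
  m <- build_model()
  m$non_hla <- c(snpX = 0.5)
  expect_equal(score_individual(m, dosages = c(snpX = 2))$total, 1.0)
  # interaction lookup replaces the additive DQ contribution entirely
  m2 <- build_model()
  m2$dq_additive <- c(A = 10, B = 20)
  m2$dq_interactions <- stats::setNames(0.7, pair_key("A", "B"))
  s <- score_individual(m2, hap_pair = c("B", "A"))
  expect_identical(s$dq_path, "interaction_lookup")
  expect_equal(s$dq, 0.7)
  # non-carrier takes the additive path
  s2 <- score_individual(m2, hap_pair = c("A", "A"))
  expect_identical(s2$dq_path, "additive")
  expect_equal(s2$dq, 20)
  # unresolved haplotypes flag the score
  s3 <- score_individual(m2, hap_pair = c(NA, NA))
  expect_true(s3$flagged)
  expect_true(is.na(s3$total))
  # missing model SNP scores as dose 0 and is counted
  m3 <- build_model(); m3$non_hla <- c(a = 1, b = 2)
  s4 <- score_individual(m3, dosages = c(a = 1))
  expect_equal(s4$total, 1)
  expect_identical(s4$n_missing_snps, 1L)
})

test_that("component decomposition and ordering invariance hold on random fixtures", {
  set.seed(101)
  for (r in 1:100) {
    m <- random_model()
    labels <- names(m$dq_additive)
    hap_pair <- sample(c(labels, labels), 2)
    dos <- stats::setNames(runif(9, 0, 2),
                           sample(c(names(m$hla_other), names(m$non_hla))))
    s <- score_individual(m, hap_pair, dos)
    expect_equal(s$total, s$dq + s$hla_other + s$non_hla, tolerance = 1e-9)
    # shuffling the stored SNP order never changes the score
    m2 <- m
    m2$non_hla <- m$non_hla[sample(names(m$non_hla))]
    m2$hla_other <- m$hla_other[sample(names(m$hla_other))]
    expect_equal(score_individual(m2, hap_pair, dos)$total, s$total,
                 tolerance = 1e-12)
    # empty interaction table reduces exactly to the additive sum
    m3 <- m; m3$dq_interactions <- numeric(0)
    s3 <- score_individual(m3, hap_pair, dos)
    add <- sum(m$dq_additive[hap_pair], na.rm = TRUE) +
      sum(m$hla_other * ifelse(is.na(dos[names(m$hla_other)]), 0,
                               dos[names(m$hla_other)])) +
      sum(m$non_hla * ifelse(is.na(dos[names(m$non_hla)]), 0,
                             dos[names(m$non_hla)]))
    expect_equal(s3$total, add, tolerance = 1e-9)
    expect_identical(s3$dq_path, "additive")
  }
})

test_that("cohort scoring is deterministic, linear in dosage, and separates groups", {
  set.seed(5)
  m <- build_model()
  m$non_hla <- c(s1 = 0.6, s2 = -0.3)
  D <- matrix(rbinom(40, 2, 0.4), ncol = 2,
              dimnames = list(sprintf("I%02d", 1:20), c("s1", "s2")))
  sc <- score_cohort(m, dosages = D)
  # identical individuals get identical scores
  D2 <- rbind(D, D[1, , drop = FALSE])
  rownames(D2)[21] <- "I21"
  sc2 <- score_cohort(m, dosages = D2)
  expect_equal(sc2$total[21], sc2$total[1])
  # +1 dose of a beta = 0.6 SNP raises the total by exactly 0.6
  D3 <- D; D3[1, "s1"] <- D[1, "s1"] + 1
  sc3 <- score_cohort(m, dosages = D3)
  expect_equal(sc3$total[1] - sc$total[1], 0.6, tolerance = 1e-12)
  # strong simulated effects: median case score exceeds median control score
  cfg <- sim_config(n_cases = 500, n_controls = 500, tag_specs = NULL,
                    seed = 33)
  co <- simulate_cohort(cfg)
  pool <- cfg$haplotype_pool
  mt <- build_model()
  mt$dq_additive <- stats::setNames(pool$beta, pool$label)
  mt$non_hla <- stats::setNames(cfg$nonhla_snps$beta, cfg$nonhla_snps$id)
  st <- score_cohort(mt, cohort = co)
  expect_gt(median(st$total[co$phenotype == 1]),
            median(st$total[co$phenotype == 0]))
})

test_that("model JSON and weight sheet round-trip", {
  set.seed(55)
  m <- random_model()
  m$metadata$cohort <- "unit-test"
  d <- withr::local_tempdir()
  f <- file.path(d, "model.json")
  save_model(m, f, sheet = TRUE)
  m2 <- load_model(f)
  expect_equal(m2$dq_additive, m$dq_additive)
  expect_equal(m2$dq_interactions, m$dq_interactions)
  expect_equal(m2$hla_other, m$hla_other)
  expect_equal(m2$non_hla, m$non_hla)
  expect_identical(m2$version, m$version)
  # weight sheet re-import preserves the additive weights
  w <- read_weights(paste0(f, ".weights.tsv"))
  nh <- w[w$term_type == "non_hla", ]
  expect_equal(stats::setNames(nh$beta, nh$id), m$non_hla)
  # unknown fields warn and are preserved in metadata
  obj <- jsonlite::read_json(f)
  obj$mystery_field <- "kept"
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  expect_warning(m3 <- load_model(f), "mystery_field")
  expect_identical(m3$metadata$extra$mystery_field, "kept")
  # schema version errors are explicit
  obj$version <- "9.9"
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(f), "version")
})

test_that("incremental AUC starts at the DQ base and ignores null additions", {
  set.seed(77)
  n <- 800
  labels <- c("Ha", "Hb")
  hp <- cbind(sample(labels, n, TRUE, prob = c(0.7, 0.3)),
              sample(labels, n, TRUE, prob = c(0.7, 0.3)))
  m <- build_model()
  m$dq_additive <- c(Ha = 0, Hb = 1.2)
  m$non_hla <- c(info = 0.9, null = 0)
  D <- matrix(rbinom(2 * n, 2, 0.3), ncol = 2,
              dimnames = list(NULL, c("info", "null")))
  eta <- m$dq_additive[hp[, 1]] + m$dq_additive[hp[, 2]] + 0.9 * D[, "info"]
  y <- rbinom(n, 1, plogis(-1 + eta))
  curve <- incremental_auc(m, hp, D, y, ranked_snps = c("info", "null"))
  mdq <- m; mdq$non_hla <- numeric(0); mdq$hla_other <- numeric(0)
  dq_only <- score_cohort(mdq, hap_pairs = hp, dosages = D)$total
  expect_equal(curve$auc[1], roc_auc(dq_only, y)$auc)
  # a zero-weight SNP changes nothing
  expect_equal(curve$auc[3], curve$auc[2], tolerance = 1e-12)
  expect_equal(curve$p_vs_prev[3], 1)
})

test_that("plateau detection lands after the informative prefix in most seeds", {
  hits <- 0
  for (s in 1:15) {
    set.seed(400 + s)
    n <- 1500
    betas <- c(i1 = 0.9, i2 = 0.8, i3 = 0.7, n1 = 0, n2 = 0, n3 = 0, n4 = 0,
               n5 = 0)
    D <- matrix(rbinom(n * 8, 2, 0.3), ncol = 8,
                dimnames = list(NULL, names(betas)))
    y <- rbinom(n, 1, plogis(-0.8 + drop(D %*% betas)))
    m <- build_model()
    m$non_hla <- betas
    curve <- incremental_auc(m, hap_pairs = NULL, dosages = D, y = y,
                             ranked_snps = names(betas))
    pl <- attr(curve, "plateau")
    hits <- hits + (!is.na(pl) && pl %in% 3:5)
  }
  expect_gte(hits, 11) # >= ~90% allowing binomial noise at 15 seeds
})
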
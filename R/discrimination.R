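#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney concordance probability: the proportion of
#' (case, control) pairs in which the case scores higher, ties counted
#' one half. The full curve is emitted with thresholds applied as
#' "score > t calls a case", including the (FPR, TPR) endpoints (0,1) and
#' (1,0).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (1 = case); both classes must be present.
#' @return Object of class `roc_curve`: list `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  stop_if_not(n_pos > 0 && n_neg > 0, "need at least one case and one control")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  # call positive when score > t: one operating point per distinct score,
  # plus the all-negative point
  tp <- vapply(thr, function(t) sum(scores > t & labels == 1L), 0)
  fp <- vapply(thr, function(t) sum(scores > t & labels == 0L), 0)
  thresholds <- c(Inf, thr)
  sens <- c(0, tp / n_pos, 1)
  spec <- c(1, 1 - fp / n_neg, 0)
  thresholds <- c(thresholds, -Inf)
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: AUC = %.4f (%d cases, %d controls)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "l",
                 xlab = "1 - specificity", ylab = "Sensitivity", ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision convention: precision at each distinct threshold,
#' weighted by the recall increment it contributes (step-wise integration;
#' trapezoids overestimate PR curves and are not used).
#'
#' @inheritParams roc_auc
#' @return PRAUC value.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels == 1L)
  stop_if_not(n_pos > 0 && sum(labels == 0L) > 0,
              "need at least one case and one control")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp_at <- cumsum(vapply(thr, function(t) sum(scores == t & labels == 1L), 0))
  n_at <- cumsum(vapply(thr, function(t) sum(scores == t), 0))
  precision <- tp_at / n_at
  recall <- tp_at / n_pos
  sum(precision * diff(c(0, recall)))
}

# DeLong structural components: V10 (one per case), V01 (one per control)
delong_placements <- function(scores, labels) {
  X <- scores[labels == 1L]; Y <- scores[labels == 0L]
  m <- length(X); n <- length(Y)
  # midrank trick: placements from the joint and marginal ranks
  r_all <- rank(c(X, Y), ties.method = "average")
  rX <- rank(X, ties.method = "average")
  rY <- rank(Y, ties.method = "average")
  V10 <- (r_all[seq_len(m)] - rX) / n
  V01 <- 1 - (r_all[m + seq_len(n)] - rY) / m
  list(V10 = V10, V01 = V01, auc = mean(V10))
}

delong_result <- function(auc1, auc2, var_diff, design) {
  d <- auc1 - auc2
  if (var_diff <= 0) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else z <- d / sqrt(var_diff)
  p <- if (is.infinite(z)) .Machine$double.xmin else max(2 * stats::pnorm(-abs(z)),
                                                          .Machine$double.xmin)
  if (z == 0) p <- 1
  structure(list(auc1 = auc1, auc2 = auc2, var_diff = var_diff, z = z, p = p,
                 design = design), class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong %s test: AUC %.4f vs %.4f, z = %.3f, p = %.3g\n",
              x$design, x$auc1, x$auc2, x$z, x$p))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Both scores are measured on the same individuals; the variance of the
#' AUC difference uses the DeLong structural-components covariance
#' estimate, with a two-sided normal p-value. Identical (or rank-identical)
#' score vectors give z = 0, p = 1.
#'
#' @param scores_a,scores_b Score vectors on the same individuals.
#' @param labels Shared 0/1 labels.
#' @return Object of class `delong_result` (`auc1`, `auc2`, `var_diff`,
#'   `z`, `p`, `design = "paired"`).
#' @export
delong_paired <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  stop_if_not(length(scores_a) == length(scores_b) &&
              length(scores_a) == length(labels),
              "paired design requires equal-length inputs")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- length(pa$V10); n <- length(pa$V01)
  s10 <- stats::cov(cbind(pa$V10, pb$V10))
  s01 <- stats::cov(cbind(pa$V01, pb$V01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delong_result(pa$auc, pb$auc, var_diff, "paired")
}

# DeLong variance of a single AUC
delong_auc_var <- function(scores, labels) {
  p <- delong_placements(scores, labels)
  stats::var(p$V10) / length(p$V10) + stats::var(p$V01) / length(p$V01)
}

#' Unpaired DeLong test for AUCs from disjoint samples
#'
#' The variance of the difference is the sum of the per-sample DeLong AUC
#' variances; two-sided normal p-value.
#'
#' @param scores_1,labels_1 First stratum.
#' @param scores_2,labels_2 Second stratum (disjoint individuals).
#' @return Object of class `delong_result` with `design = "unpaired"`.
#' @export
delong_unpaired <- function(scores_1, labels_1, scores_2, labels_2) {
  l1 <- as.integer(labels_1); l2 <- as.integer(labels_2)
  stop_if_not(sum(l1 == 1L) > 0 && sum(l1 == 0L) > 0 &&
              sum(l2 == 1L) > 0 && sum(l2 == 0L) > 0,
              "each stratum needs both classes")
  a1 <- roc_auc(scores_1, l1)$auc
  a2 <- roc_auc(scores_2, l2)$auc
  var_diff <- delong_auc_var(scores_1, l1) + delong_auc_var(scores_2, l2)
  delong_result(a1, a2, var_diff, "unpaired")
}

#' Centile-based cutoff table
#'
#' For each requested specificity, the threshold is the matching empirical
#' centile (type-7 quantile) of the negative group; a score above the
#' threshold calls the positive class (`direction = "greater"`, matching
#' a "score > t" rule). `direction = "less"` supports the dual rule — a
#' low threshold below which the negative class is called with the stated
#' specificity against the positive group. Achieved sensitivity,
#' specificity and the threshold's centile within each group are reported.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param specificity_grid Requested specificities in (0, 1).
#' @param direction `"greater"` (default) or `"less"`.
#' @return data.frame of class `cutoff_table`: `specificity_requested
#'   threshold sensitivity specificity centile_neg centile_pos`.
#' @export
cutoff_table <- function(scores, labels, specificity_grid = c(0.90, 0.95, 0.99),
                         direction = c("greater", "less")) {
  direction <- match.arg(direction)
  labels <- as.integer(labels)
  stop_if_not(all(specificity_grid > 0 & specificity_grid < 1),
              "requested specificities must lie in (0, 1)")
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  stop_if_not(length(pos) > 0 && length(neg) > 0,
              "need at least one case and one control")
  rows <- lapply(sort(specificity_grid), function(s) {
    if (direction == "greater") {
      t <- unname(stats::quantile(neg, s, type = 7))
      sens <- mean(pos > t); spec <- mean(neg <= t)
    } else {
      t <- unname(stats::quantile(pos, 1 - s, type = 7))
      sens <- mean(neg < t); spec <- mean(pos >= t)
    }
    data.frame(specificity_requested = s, threshold = t, sensitivity = sens,
               specificity = spec, centile_neg = 100 * mean(neg <= t),
               centile_pos = 100 * mean(pos <= t))
  })
  out <- do.call(rbind, rows)
  attr(out, "direction") <- direction
  class(out) <- c("cutoff_table", class(out))
  out
}

#' Tertile assignment by type-7 quantiles
#'
#' @param values Numeric vector.
#' @return Factor with levels `low`, `mid`, `high`.
#' @export
tertiles <- function(values) {
  q <- stats::quantile(values, c(1, 2) / 3, type = 7, na.rm = TRUE)
  cut(values, breaks = c(-Inf, q, Inf), labels = c("low", "mid", "high"),
      include.lowest = TRUE)
}

#' Compare a continuous variable across groups
#'
#' Two groups: Welch t-test (parametric) or Mann-Whitney (non-parametric);
#' more than two: one-way ANOVA or Kruskal-Wallis. Group medians and IQRs
#' are reported alongside the test.
#'
#' @param values Numeric vector.
#' @param groups Group labels aligned to `values` (>= 2 non-empty groups).
#' @param mode `"nonparametric"` (default) or `"parametric"`.
#' @return List of class `group_comparison`: `method`, `p`, `statistic`,
#'   `groups` (data.frame of n/median/IQR per group).
#' @export
stratify_and_compare <- function(values, groups,
                                 mode = c("nonparametric", "parametric")) {
  mode <- match.arg(mode)
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  stop_if_not(nlevels(groups) >= 2, "need at least two non-empty groups")
  stop_if_not(all(table(groups) > 0), "empty group")
  if (nlevels(groups) == 2L) {
    tst <- if (mode == "parametric")
      stats::t.test(values ~ groups)
    else stats::wilcox.test(values ~ groups, exact = FALSE)
  } else {
    tst <- if (mode == "parametric")
      summary(stats::aov(values ~ groups))[[1]]
    else stats::kruskal.test(values, groups)
  }
  if (inherits(tst, "htest")) {
    p <- tst$p.value; stat <- unname(tst$statistic); method <- tst$method
  } else { # aov summary table
    p <- tst[["Pr(>F)"]][1]; stat <- tst[["F value"]][1]; method <- "One-way ANOVA"
  }
  gs <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25, type = 7)),
               q3 = unname(stats::quantile(v, 0.75, type = 7)))
  }))
  structure(list(method = method, p = p, statistic = stat, groups = gs,
                 mode = mode), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: p = %.3g\n", x$method, x$p))
  print(x$groups, row.names = FALSE)
  invisible(x)
}
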
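# ROC / AUC analysis with cut-off selection, and the association tests used
# in the cut-out risk analysis (chi-square with exact fallback,
# Mann-Whitney, proportion summaries).

#' AUC by the Mann-Whitney pair-count formula
#'
#' AUC = (number of positive > negative pairs + 0.5 * ties) /
#' (n_pos * n_neg), computed via rank sums; identical to the trapezoidal
#' area under the empirical ROC curve.
#'
#' @param scores_pos Scores of the outcome-positive group.
#' @param scores_neg Scores of the outcome-negative group.
#' @return AUC in [0, 1] for the rule "higher score indicates the positive
#'   class".
#' @export
auc_mann_whitney <- function(scores_pos, scores_neg) {
  m <- length(scores_pos); n <- length(scores_neg)
  if (m < 1L || n < 1L)
    stop_mtad("insufficient_data", "both outcome groups must be non-empty")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Empirical ROC curve
#'
#' Thresholds are midpoints between adjacent distinct observed scores,
#' bracketed by -Inf and +Inf, for the rule "score >= threshold is called
#' positive".
#'
#' @inheritParams auc_mann_whitney
#' @return A `data.frame` with columns `threshold`, `tpr`, `fpr`, ordered by
#'   decreasing threshold (so the curve runs from (0,0) to (1,1)).
#' @export
roc_curve <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg))
    stop_mtad("insufficient_data", "both outcome groups must be non-empty")
  v <- sort(unique(c(scores_pos, scores_neg)))
  thr <- if (length(v) > 1) (v[-1] + v[-length(v)]) / 2 else numeric(0)
  thr <- c(Inf, rev(thr), -Inf)
  tpr <- vapply(thr, function(t) mean(scores_pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores_neg >= t), numeric(1))
  data.frame(threshold = thr, tpr = tpr, fpr = fpr)
}

#' Youden-optimal cut-off
#'
#' Selects the threshold maximising Youden's J = sensitivity + specificity
#' - 1 over the midpoint grid of [roc_curve()]; ties are broken toward the
#' higher specificity (the larger threshold under the "higher = risk"
#' orientation).  When every score is identical, J = 0 everywhere and the
#' result is flagged degenerate.
#'
#' @inheritParams auc_mann_whitney
#' @return A list: `cutoff`, `sensitivity_pct`, `specificity_pct`,
#'   `youden_j`, `degenerate`.
#' @export
youden_cutoff <- function(scores_pos, scores_neg) {
  rc <- roc_curve(scores_pos, scores_neg)
  j <- rc$tpr - rc$fpr
  degenerate <- max(j) <= 0
  # finite thresholds only; rc is ordered by decreasing threshold, and
  # which.max takes the first (largest-threshold, highest-specificity) tie
  finite <- which(is.finite(rc$threshold))
  cand <- if (length(finite)) finite else seq_len(nrow(rc))
  best <- cand[which.max(j[cand])]
  list(cutoff = rc$threshold[best],
       sensitivity_pct = 100 * rc$tpr[best],
       specificity_pct = 100 * (1 - rc$fpr[best]),
       youden_j = j[best],
       degenerate = degenerate)
}

#' DeLong confidence interval for the AUC
#'
#' Nonparametric (DeLong) variance of the Mann-Whitney AUC from the
#' placement values of each group; Wald interval on the AUC scale, clipped
#' to [0, 1].
#'
#' @inheritParams auc_mann_whitney
#' @param level Confidence level (default 0.95).
#' @return A list: `auc`, `ci_low`, `ci_high`, `se`.
#' @export
auc_confidence_interval <- function(scores_pos, scores_neg, level = 0.95) {
  m <- length(scores_pos); n <- length(scores_neg)
  if (m < 2L || n < 2L)
    stop_mtad("insufficient_data", "DeLong CI needs >= 2 cases per group")
  psi <- outer(scores_pos, scores_neg,
               function(x, y) (x > y) + 0.5 * (x == y))
  auc <- mean(psi)
  v10 <- rowMeans(psi)   # placement of each positive among the negatives
  v01 <- colMeans(psi)
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = auc,
       ci_low = max(0, auc - z * se),
       ci_high = min(1, auc + z * se),
       se = se)
}

#' Full ROC analysis of one parameter
#'
#' Combines AUC, DeLong CI, and Youden cut-off for one continuous position
#' parameter against the binary cut-out outcome.  The risk direction is
#' detected automatically: if AUC for "higher = risk" falls below 0.5 the
#' scores are negated (e.g. the axis-blade angle, where lower values flag
#' risk) and the reported cut-off is mapped back to the original scale.
#'
#' @param scores Numeric parameter values.
#' @param outcome Logical (or 0/1) cut-out indicator, same length.
#' @param parameter_name Label carried into the result.
#' @param higher_is_risk `NA` (default) to auto-detect, otherwise force the
#'   orientation.
#' @return An object of class `roc_result`: a list with `parameter_name`,
#'   `auc`, `ci_low`, `ci_high`, `p_value` (Mann-Whitney), `cutoff`,
#'   `cutoff_reported` (snapped to the nearest integer, the resolution of
#'   clinical threshold tables), `sensitivity_pct`, `specificity_pct`,
#'   `higher_is_risk`, `n_pos`, `n_neg`, `curve`.
#' @export
roc_analysis <- function(scores, outcome, parameter_name = "score",
                         higher_is_risk = NA) {
  keep <- is.finite(scores) & !is.na(outcome)
  scores <- scores[keep]; outcome <- as.logical(outcome[keep])
  pos <- scores[outcome]; neg <- scores[!outcome]
  if (!length(pos) || !length(neg))
    stop_mtad("degenerate_outcome",
              "outcome has no variation among usable cases")
  if (is.na(higher_is_risk))
    higher_is_risk <- auc_mann_whitney(pos, neg) >= 0.5
  s_pos <- if (higher_is_risk) pos else -pos
  s_neg <- if (higher_is_risk) neg else -neg
  auc <- auc_mann_whitney(s_pos, s_neg)
  ci <- if (length(pos) >= 2L && length(neg) >= 2L)
    auc_confidence_interval(s_pos, s_neg)
  else list(ci_low = NA_real_, ci_high = NA_real_)
  yc <- youden_cutoff(s_pos, s_neg)
  mw <- mann_whitney_test(pos, neg)
  cutoff <- if (higher_is_risk) yc$cutoff else -yc$cutoff
  structure(list(
    parameter_name = parameter_name,
    auc = auc, ci_low = ci$ci_low, ci_high = ci$ci_high,
    p_value = mw$p_value,
    cutoff = cutoff,
    cutoff_reported = round(cutoff),
    sensitivity_pct = yc$sensitivity_pct,
    specificity_pct = yc$specificity_pct,
    youden_degenerate = yc$degenerate,
    higher_is_risk = higher_is_risk,
    n_pos = length(pos), n_neg = length(neg),
    curve = roc_curve(s_pos, s_neg)
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result %s> AUC %.3f (95%% CI %.3f-%.3f), cutoff %s (%s), sens %.1f%%, spec %.1f%%\n",
    x$parameter_name, x$auc, x$ci_low, x$ci_high,
    format(round(x$cutoff, 2)),
    if (x$higher_is_risk) ">= flags risk" else "<= flags risk",
    x$sensitivity_pct, x$specificity_pct))
  invisible(x)
}

#' Chi-square association test with exact fallback
#'
#' Pearson chi-square on an r x c contingency table; when any expected cell
#' count falls below 5 the p-value is taken from Fisher's exact test
#' instead, and `method_used` records the switch.  The Pearson statistic is
#' reported in either case.
#'
#' @param counts Non-negative integer matrix, at least 2 x 2.
#' @return A list: `statistic`, `df`, `p_value`, `method_used`
#'   (`"pearson"` or `"fisher_exact"`), `expected`.
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L || any(counts < 0))
    stop_mtad("degenerate_table", "need a non-negative table of at least 2 x 2")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop_mtad("degenerate_table", "zero-margin row or column")
  pear <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(pear$expected < 5)) {
    p <- stats::fisher.test(counts, workspace = 2e6)$p.value
    method <- "fisher_exact"
  } else {
    p <- pear$p.value
    method <- "pearson"
  }
  list(statistic = unname(pear$statistic), df = unname(pear$parameter),
       p_value = p, method_used = method, expected = pear$expected)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided; exact enumeration for small untied samples (both groups at
#' most 20), normal approximation with tie correction otherwise.
#'
#' @param group_a,group_b Numeric vectors.
#' @return A list: `U` (for `group_a`), `p_value`, `exact`.
#' @export
mann_whitney_test <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (!length(group_a) || !length(group_b))
    stop_mtad("insufficient_data", "both groups must be non-empty")
  ties <- any(duplicated(c(group_a, group_b)))
  exact <- !ties && max(length(group_a), length(group_b)) <= 20L
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Relative frequency as a percentage, 1 decimal
#'
#' 100 * count / total, rounded half-up to one decimal -- the convention of
#' clinical frequency tables (e.g. 13 of 109 -> 11.9).
#'
#' @param count,total Non-negative integers, `count <= total`, `total > 0`.
#' @return Percentage rounded to 1 decimal.
#' @export
proportion_summary <- function(count, total) {
  if (any(total <= 0)) stop_mtad("degenerate_table", "total must be positive")
  if (any(count < 0) || any(count > total))
    stop_mtad("degenerate_table", "count must be within [0, total]")
  unname(floor(1000 * count / total + 0.5) / 10)
}
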
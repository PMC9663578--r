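#' Labeled specimen scores
#'
#' Pairs one labeling parameter's percentage values (one per specimen) with a
#' binary reference classification, e.g. an activating mutation call or
#' TKI-therapy response. The positive class drives sensitivity; for ROC
#' analysis both classes must be represented.
#'
#' @param values Numeric scores (percentages).
#' @param labels Logical (or 0/1) reference labels, `TRUE` = positive class.
#' @param parameter_name Optional label, e.g. `"EGFR(+)HX103(+)"`.
#' @return An object of class `labeled_scores`.
#' @export
labeled_scores <- function(values, labels, parameter_name = "score") {
  labels <- as.logical(labels)
  if (length(values) != length(labels))
    stop("'values' and 'labels' must have equal length", call. = FALSE)
  keep <- is.finite(values) & !is.na(labels)
  structure(list(values = values[keep], labels = labels[keep],
                 parameter_name = parameter_name),
            class = "labeled_scores")
}

# tie-corrected pair statistic: P(pos > neg) + 0.5 P(pos == neg)
auc_pair_statistic <- function(pos, neg) {
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# empirical ROC points under the rule "positive if value >= threshold",
# thresholds swept from above the maximum down through every distinct value
roc_curve_points <- function(pos, neg) {
  cuts <- c(Inf, sort(unique(c(pos, neg)), decreasing = TRUE))
  tpr <- vapply(cuts, function(ct) mean(pos >= ct), numeric(1))
  fpr <- vapply(cuts, function(ct) mean(neg >= ct), numeric(1))
  data.frame(threshold = cuts, fpr = fpr, tpr = tpr)
}

trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' ROC curve and AUC with a tie-corrected pair statistic
#'
#' Computes the empirical ROC curve and its area two ways -- as the
#' trapezoidal area under the curve and as the tie-corrected pair statistic
#' `(#\{pos > neg\} + 0.5 #\{pos = neg\}) / (n_pos n_neg)` -- and asserts the
#' two agree (they are algebraically identical; exact ties across classes
#' contribute one half). The standard error uses the Hanley-McNeil formula
#' and the 95% interval is the uncapped Wald interval `auc +/- 1.96 se`, so
#' the upper bound may exceed 1. The Youden-optimal cut-off is included.
#'
#' @param scores A [labeled_scores()] object with both classes present.
#' @return An object of class `roc_result`: `points` (threshold/fpr/tpr data
#'   frame), `auc`, `se_auc`, `ci95`, `youden_cutoff`, `youden_j`, `n_pos`,
#'   `n_neg`.
#' @examples
#' s <- labeled_scores(c(5, 9, 1, 8, 7, 2), c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
#' roc_auc(s)$auc
#' @export
roc_auc <- function(scores) {
  stopifnot(inherits(scores, "labeled_scores"))
  pos <- scores$values[scores$labels]
  neg <- scores$values[!scores$labels]
  if (length(pos) == 0 || length(neg) == 0)
    stop("undefined ROC: both classes must be non-empty", call. = FALSE)
  auc <- auc_pair_statistic(pos, neg)
  pts <- roc_curve_points(pos, neg)
  area <- trapezoid_area(pts$fpr, pts$tpr)
  stopifnot(abs(area - auc) < 1e-12)  # duality of the two computations
  n1 <- length(pos); n2 <- length(neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  yj <- tryCatch(youden_cutoff(scores), error = function(e) NULL)
  structure(list(points = pts, auc = auc, se_auc = se,
                 ci95 = auc + c(-1, 1) * 1.96 * se,
                 youden_cutoff = if (is.null(yj)) NA_real_ else yj$cutoff,
                 youden_j = if (is.null(yj)) NA_real_ else yj$j,
                 n_pos = n1, n_neg = n2,
                 parameter_name = scores$parameter_name),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC for %s: AUC = %.3f (HM se %.3f, 95%% CI %.3f-%.3f), %d pos vs %d neg\n",
              x$parameter_name, x$auc, x$se_auc, x$ci95[1], x$ci95[2],
              x$n_pos, x$n_neg))
  cat(sprintf("  Youden cut-off %.4g (J = %.3f)\n", x$youden_cutoff, x$youden_j))
  invisible(x)
}

#' Youden-optimal midpoint cut-off
#'
#' Candidate cut-offs are the midpoints between consecutive distinct sorted
#' score values; each is evaluated under the decision rule "positive if
#' value >= cutoff" and the candidate maximising the Youden index
#' J = sensitivity + specificity - 1 is returned. Ties in J are broken
#' toward the cut-off with higher sensitivity (the lower cut-off).
#'
#' @param scores A [labeled_scores()] with both classes present.
#' @return A list: `cutoff`, `j`, `sensitivity`, `specificity` (fractions).
#' @export
youden_cutoff <- function(scores) {
  stopifnot(inherits(scores, "labeled_scores"))
  pos <- scores$values[scores$labels]
  neg <- scores$values[!scores$labels]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes must be non-empty", call. = FALSE)
  v <- sort(unique(scores$values))
  if (length(v) < 2)
    stop("no cut-off: all score values are identical", call. = FALSE)
  cands <- (utils::head(v, -1) + utils::tail(v, -1)) / 2
  sens <- vapply(cands, function(ct) mean(pos >= ct), numeric(1))
  spec <- vapply(cands, function(ct) mean(neg < ct), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(sens[best])]  # prefer higher sensitivity on J ties
  list(cutoff = cands[best], j = j[best],
       sensitivity = sens[best], specificity = spec[best])
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Beta-quantile form of the exact interval for a binomial proportion,
#' returned in percent. The lower bound is 0 when `k = 0` and the upper
#' bound 100 when `k = n`.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(lo, hi)` in percent.
#' @examples
#' clopper_pearson(10, 12)  # c(51.6, 97.9) to one decimal
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    stop("need integers 0 <= k <= n with n >= 1", call. = FALSE)
  alpha <- 1 - level
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lo = 100 * lo, hi = 100 * hi)
}

#' Confusion matrix at a fixed cut-off
#'
#' Applies the decision rule "positive if value >= cutoff" and summarises the
#' resulting confusion matrix: counts, sensitivity, specificity and accuracy
#' in percent, each with its exact Clopper-Pearson 95% interval.
#'
#' @param scores A [labeled_scores()].
#' @param cutoff Decision threshold (same units as the scores).
#' @return An object of class `confusion_summary` with fields `tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `specificity`, `accuracy` (percent) and
#'   `sensitivity_ci`, `specificity_ci`, `accuracy_ci`.
#' @export
confusion <- function(scores, cutoff) {
  stopifnot(inherits(scores, "labeled_scores"), is.finite(cutoff))
  called_pos <- scores$values >= cutoff
  tp <- sum(called_pos & scores$labels)
  fp <- sum(called_pos & !scores$labels)
  fn <- sum(!called_pos & scores$labels)
  tn <- sum(!called_pos & !scores$labels)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, cutoff = cutoff,
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 accuracy = 100 * (tp + tn) / (tp + fp + tn + fn),
                 sensitivity_ci = clopper_pearson(tp, tp + fn),
                 specificity_ci = clopper_pearson(tn, tn + fp),
                 accuracy_ci = clopper_pearson(tp + tn, tp + fp + tn + fn),
                 parameter_name = scores$parameter_name),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("Confusion matrix for %s at cut-off %.4g:\n", x$parameter_name,
              x$cutoff))
  cat(sprintf("  TP %d  FN %d  |  FP %d  TN %d\n", x$tp, x$fn, x$fp, x$tn))
  cat(sprintf("  sensitivity %.1f%% (95%% CI %.1f-%.1f)\n", x$sensitivity,
              x$sensitivity_ci[1], x$sensitivity_ci[2]))
  cat(sprintf("  specificity %.1f%% (95%% CI %.1f-%.1f)\n", x$specificity,
              x$specificity_ci[1], x$specificity_ci[2]))
  cat(sprintf("  accuracy    %.1f%% (95%% CI %.1f-%.1f)\n", x$accuracy,
              x$accuracy_ci[1], x$accuracy_ci[2]))
  invisible(x)
}

#' Mann-Whitney U test (exact for small untied samples)
#'
#' U is reported with the pair-count convention `#\{x > y\} + 0.5 #\{x = y\}`.
#' With `min(n, m) <= 8` and no tied values anywhere in the pooled sample the
#' two-sided p-value comes from the exact null distribution of U; otherwise a
#' tie-corrected normal approximation without continuity correction is used
#' (so two identical samples give p = 1 on the approximation path).
#'
#' @param x,y Numeric samples, both non-empty.
#' @return A list: `u`, `p`, `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  n <- length(x); m <- length(y)
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(x, y)
  has_ties <- anyDuplicated(pooled) > 0
  if (!has_ties && min(n, m) <= 8) {
    p <- if (u > n * m / 2)
      stats::pwilcox(u - 1, n, m, lower.tail = FALSE)
    else
      stats::pwilcox(u, n, m)
    return(list(u = u, p = min(2 * p, 1), method = "exact"))
  }
  N <- n + m
  ties <- table(pooled)
  sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(u = u, p = 1, method = "normal"))
  z <- (u - n * m / 2) / sqrt(sigma2)
  list(u = u, p = min(2 * stats::pnorm(-abs(z)), 1), method = "normal")
}

#' Per-class mean, SD and SEM
#'
#' @param scores A [labeled_scores()].
#' @return A data frame with one row per class (`positive`, `negative`):
#'   `n`, `mean`, `sd`, `sem`. For single-member classes `sd` and `sem` are
#'   `NA`.
#' @export
group_summary <- function(scores) {
  stopifnot(inherits(scores, "labeled_scores"))
  one <- function(v) {
    s <- if (length(v) > 1) stats::sd(v) else NA_real_
    data.frame(n = length(v), mean = mean(v), sd = s,
               sem = s / sqrt(length(v)))
  }
  out <- rbind(one(scores$values[scores$labels]),
               one(scores$values[!scores$labels]))
  cbind(class = c("positive", "negative"), out)
}

#' Pearson correlation with two-sided t-test p-value
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, each with non-zero
#'   variance.
#' @return A list: `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in 'x' or 'y'", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Round for display the way clinical tables print
#'
#' Plain half-away-from-zero rounding (36.25 -> 36.3), as opposed to the
#' IEC half-to-even rule used by [round()]. Used when echoing cut-offs and
#' percentages next to their printed one-decimal forms; analyses always use
#' full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places, default 1.
#' @return Rounded numeric vector.
#' @export
display_round <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
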
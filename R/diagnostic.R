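# ROC/AUC analysis with DeLong interval, left-upper-corner optimal cutoff,
# 2x2 diagnostic metrics, and percent coefficient of variation.

#' Empirical ROC curve with AUC and DeLong confidence interval
#'
#' Sweeps every distinct score as a threshold (test positive when the score
#' exceeds it, for `positive_direction = "greater"`) and records the
#' (false-positive rate, true-positive rate) operating points from (0,0) to
#' (1,1). AUC is the Mann-Whitney statistic with ties counted one half —
#' identical to the trapezoidal area over the points — and the 95% interval
#' uses the DeLong placement-value variance estimator.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical); 1 = positive class.
#' @param positive_direction `"greater"` if positives score high (default),
#'   `"less"` if they score low.
#' @param conf_level Confidence level for the AUC interval (default 0.95).
#' @return Object of class `roc_result`: `points` (data frame `threshold`,
#'   `fpr`, `tpr`, ordered by increasing fpr), `auc`, `auc_ci`,
#'   `positive_direction`, `n_pos`, `n_neg`.
#' @examples
#' roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc  # 1
#' @export
roc_curve <- function(scores, labels, positive_direction = c("greater", "less"),
                      conf_level = 0.95) {
  positive_direction <- match.arg(positive_direction)
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores and labels must align")
  ok <- stats::complete.cases(scores, labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!all(c(0L, 1L) %in% labels))
    stop("both classes must be present for a ROC curve")
  s <- if (positive_direction == "greater") scores else -scores

  pos <- s[labels == 1L]; neg <- s[labels == 0L]
  n1 <- length(pos); n0 <- length(neg)

  # operating points: threshold t -> positive if s > t
  thr <- c(-Inf, sort(unique(s)))
  tpr <- vapply(thr, function(t) mean(pos > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg > t), numeric(1))
  ord <- order(fpr, tpr)
  pts <- data.frame(threshold = thr[ord], fpr = fpr[ord], tpr = tpr[ord])

  # DeLong placement values
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), numeric(1))
  auc <- mean(v10)
  var_auc <- stats::var(v10) / n1 + stats::var(v01) / n0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(var_auc), 0), 1)

  # map thresholds back to the original score scale
  if (positive_direction == "less") {
    pts$threshold <- -pts$threshold
  }
  structure(
    list(points = pts, auc = auc, auc_ci = ci,
         positive_direction = positive_direction,
         n_pos = n1, n_neg = n0),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC analysis (%d positives, %d negatives; positive if score %s threshold)\n",
              x$n_pos, x$n_neg,
              if (x$positive_direction == "greater") ">" else "<"))
  cat(sprintf("  AUC = %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.2f)", x$auc),
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Left-upper-corner optimal cutoff
#'
#' Chooses the operating point closest (Euclidean distance) to the ideal
#' corner (0, 1) of the ROC plane; ties break toward higher sensitivity,
#' then toward the lower threshold. The returned cutoff is the midpoint
#' between the adjacent distinct score values straddling the chosen
#' operating point, so the reported value does not coincide with an
#' observed score.
#'
#' @param roc A `roc_result`.
#' @param scores The scores the ROC was built from.
#' @param labels The matching labels (unused beyond validation).
#' @return Cutoff on the score scale (test positive beyond it, in the
#'   ROC's positive direction).
#' @examples
#' sc <- c(1, 2, 3, 4); lb <- c(0, 0, 1, 1)
#' optimal_cutoff(roc_curve(sc, lb), sc, lb)  # 2.5
#' @export
optimal_cutoff <- function(roc, scores, labels) {
  stopifnot(inherits(roc, "roc_result"))
  pts <- roc$points
  d2 <- pts$fpr^2 + (1 - pts$tpr)^2
  if (sum(d2 == min(d2)) > 1 && all(range(pts$tpr[d2 == min(d2)]) == c(0, 1)))
    warning("degenerate ROC: tie between extreme operating points")
  best <- which(d2 == min(d2))
  best <- best[order(-pts$tpr[best],
                     if (roc$positive_direction == "greater") pts$threshold[best]
                     else -pts$threshold[best])][1]
  thr <- pts$threshold[best]
  u <- sort(unique(scores))
  if (!is.finite(thr)) return(if (thr < 0) min(u) - 1 else max(u) + 1)
  if (roc$positive_direction == "less") {
    # positive if score < cutoff: midpoint below the chosen threshold
    below <- u[u < thr]
    return(if (length(below)) (thr + max(below)) / 2 else thr - 0.5)
  }
  above <- u[u > thr]
  if (length(above)) (thr + min(above)) / 2 else thr + 0.5
}

#' 2x2 diagnostic metrics at a cutoff
#'
#' Dichotomises the scores at `cutoff` (strictly greater = test positive by
#' default, matching the convention "over the cutoff" vs "at or below") and
#' tabulates against the outcome labels. Sensitivity, specificity, PPV and
#' NPV are reported in percent; `round_display` gives the 1-decimal display
#' values while the exact fractions are retained.
#'
#' @param scores Numeric test values.
#' @param labels Binary outcome (1 = condition present).
#' @param cutoff Decision threshold.
#' @param positive_if `"greater"` (strict, default) or `"ge"`.
#' @return Object of class `diagnostic_table`: counts `tp`, `fp`, `fn`,
#'   `tn` and percent metrics `sensitivity`, `specificity`, `ppv`, `npv`,
#'   plus `display` (1-decimal rounded copies).
#' @examples
#' # 12 admitted of whom 10 test positive; 18 discharged, 7 test positive
#' tab <- confusion_at(c(rep(3, 10), rep(1, 2), rep(3, 7), rep(1, 11)),
#'                     c(rep(1, 12), rep(0, 18)), cutoff = 2)
#' tab$display["sensitivity"]  # 83.3
#' @export
confusion_at <- function(scores, labels, cutoff,
                         positive_if = c("greater", "ge")) {
  positive_if <- match.arg(positive_if)
  labels <- as.integer(as.logical(labels))
  if (length(scores) == 0L) stop("empty input")
  if (length(scores) != length(labels)) stop("scores and labels must align")
  test_pos <- if (positive_if == "greater") scores > cutoff else scores >= cutoff
  tp <- sum(test_pos & labels == 1L)
  fp <- sum(test_pos & labels == 0L)
  fn <- sum(!test_pos & labels == 1L)
  tn <- sum(!test_pos & labels == 0L)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  sens <- pct(tp, tp + fn); spec <- pct(tn, tn + fp)
  ppv <- pct(tp, tp + fp); npv <- pct(tn, tn + fn)
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
         cutoff = cutoff, positive_if = positive_if,
         display = round(c(sensitivity = sens, specificity = spec,
                           ppv = ppv, npv = npv), 1)),
    class = "diagnostic_table")
}

#' @export
print.diagnostic_table <- function(x, ...) {
  cat(sprintf("Diagnostic 2x2 at cutoff %g (positive if %s)\n",
              x$cutoff, if (x$positive_if == "greater") "> cutoff" else ">= cutoff"))
  cat(sprintf("  tp %d  fp %d\n  fn %d  tn %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' Percent coefficient of variation
#'
#' 100 * SD / mean, with the integer-rounded display value alongside the
#' exact one.
#'
#' @param mean Group mean (> 0).
#' @param sd Group standard deviation (>= 0).
#' @return List with `exact` and `display` (nearest integer).
#' @examples
#' cv_percent(2.35, 0.97)$display  # 41
#' @export
cv_percent <- function(mean, sd) {
  if (mean <= 0) stop("`mean` must be positive")
  if (sd < 0) stop("`sd` must be non-negative")
  exact <- 100 * sd / mean
  list(exact = exact, display = round(exact))
}

#' Flag an abnormal capillary refill time
#'
#' Conventional bedside rule: CRT strictly greater than 3 s is abnormal.
#'
#' @param crt Capillary refill time, seconds.
#' @param cutoff Abnormality threshold, seconds (default 3).
#' @return Logical vector.
#' @export
crt_abnormal_flag <- function(crt, cutoff = 3.0) {
  crt > cutoff
}
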
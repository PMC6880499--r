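# Paired-method agreement: Pearson correlation, Bland-Altman limits of
# agreement with a proportional-bias test, and Shrout-Fleiss intraclass
# correlation with F-based confidence intervals.

#' Pearson product-moment correlation with two-sided p-value
#'
#' Standard product-moment r with the two-sided p from the t transform on
#' n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (n >= 3, non-zero variance).
#' @return List with `r`, `p`, `n`.
#' @examples
#' pearson_r(c(1, 2, 3), c(1, 2, 4))$r  # 9 / sqrt(84)
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in `x` or `y`")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tval), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Bland-Altman agreement analysis
#'
#' Differences `a - b` are summarised against pairwise averages
#' `(a + b)/2`: bias is the mean difference, the 95% limits of agreement
#' are bias +/- 1.96 SD of the differences, and proportional bias is
#' assessed by the ordinary least-squares slope of the differences on the
#' averages with its two-sided t-test.
#'
#' @param method_a,method_b Paired measurements (>= 3 pairs).
#' @return Object of class `bland_altman`: `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `prop_slope`, `prop_slope_p`, `n_pairs`, plus the
#'   `differences` and `averages` for plotting.
#' @examples
#' ba <- bland_altman(c(2, 3, 4), c(1, 2, 3))
#' ba$bias  # 1
#' @export
bland_altman <- function(method_a, method_b) {
  if (length(method_a) != length(method_b)) stop("methods must be paired")
  ok <- stats::complete.cases(method_a, method_b)
  a <- method_a[ok]; b <- method_b[ok]
  n <- length(a)
  if (n < 3L) stop("need at least 3 pairs")
  d <- a - b
  m <- (a + b) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  if (stats::var(m) > 0) {
    fit <- stats::lm(d ~ m)
    # summary.lm warns on exact fits (e.g. a constant offset); harmless here
    sl <- suppressWarnings(summary(fit)$coefficients)
    prop_slope <- sl["m", "Estimate"]
    prop_slope_p <- sl["m", "Pr(>|t|)"]
  } else {
    prop_slope <- 0; prop_slope_p <- NA_real_
  }
  structure(
    list(bias = bias, sd_diff = sd_diff,
         loa_lower = bias - 1.96 * sd_diff, loa_upper = bias + 1.96 * sd_diff,
         prop_slope = prop_slope, prop_slope_p = prop_slope_p,
         n_pairs = n, differences = d, averages = m),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement\n")
  cat(sprintf("  bias %.3f s, SD of differences %.3f s (n = %d)\n",
              x$bias, x$sd_diff, x$n_pairs))
  cat(sprintf("  95%% limits of agreement: [%.3f, %.3f] s\n",
              x$loa_lower, x$loa_upper))
  cat(sprintf("  proportional-bias slope %.3f (p = %.4g)\n",
              x$prop_slope, x$prop_slope_p))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$averages, x$differences,
                 xlab = "average of methods (s)",
                 ylab = "difference between methods (s)",
                 main = "Bland-Altman plot", ...)
  graphics::abline(h = c(x$bias, x$loa_lower, x$loa_upper),
                   lty = c(1, 2, 2), col = c("blue", "red", "red"))
  invisible(x)
}

# ANOVA mean squares of a subjects x repeats matrix.
icc_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssb <- k * sum((row_m - grand)^2)          # between subjects
  ssc <- n * sum((col_m - grand)^2)          # between repeats (columns)
  ssw <- sum((m - row_m)^2)                  # within subjects
  sse <- ssw - ssc                           # residual (two-way)
  list(msb = ssb / (n - 1), msw = ssw / (n * (k - 1)),
       msc = ssc / (k - 1), mse = sse / ((n - 1) * (k - 1)),
       n = n, k = k)
}

#' Intraclass correlation for repeated measurements
#'
#' Computes the ICC of a complete subjects-by-repeats matrix from its ANOVA
#' mean squares, in the Shrout-Fleiss taxonomy. The one-way random model
#' (ICC(1,1) for a single measurement, ICC(1,k) for the mean of k repeats)
#' is the default: one rater re-measures each subject and repeats carry no
#' shared ordering factor. The two-way random model (ICC(2,1)/ICC(2,k)) is
#' also available. 95% confidence intervals use the corresponding
#' F-distribution formulas; the single and average forms are linked exactly
#' by the Spearman-Brown relation `k*s / (1 + (k-1)*s)`.
#'
#' @param data Numeric matrix or data frame, subjects in rows, repeats in
#'   columns; complete (no NA), >= 2 subjects and >= 2 repeats.
#' @param model `"oneway"` (default) or `"twoway_random"`.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `icc_result`: `single`, `average`, `ci_single`,
#'   `ci_average`, `model_label`, `n_subjects`, `k_repeats`, `flags`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), 4, 3, byrow = TRUE)
#' icc(m)$single  # 44/47
#' @export
icc <- function(data, model = c("oneway", "twoway_random"),
                conf_level = 0.95) {
  model <- match.arg(model)
  m <- as.matrix(data)
  if (any(is.na(m))) stop("incomplete matrix: no imputation is performed")
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need >= 2 subjects and >= 2 repeats")
  a <- icc_anova(m)
  n <- a$n; k <- a$k
  alpha <- 1 - conf_level
  flags <- character(0)
  if (a$msb <= a$msw) flags <- c(flags, "no_between_subject_variance")

  if (model == "oneway") {
    single <- (a$msb - a$msw) / (a$msb + (k - 1) * a$msw)
    f_obs <- a$msb / a$msw
    fl <- f_obs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- f_obs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    ci_single <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    label <- "one-way random, ICC(1,1)/ICC(1,k)"
  } else {
    single <- (a$msb - a$mse) /
      (a$msb + (k - 1) * a$mse + k * (a$msc - a$mse) / n)
    # Shrout-Fleiss ICC(2,1) interval via the Satterthwaite-style df `v`
    aa <- k * single / (n * (1 - single))
    bb <- 1 + k * single * (n - 1) / (n * (1 - single))
    v <- (aa * a$msc + bb * a$mse)^2 /
      ((aa * a$msc)^2 / (k - 1) + (bb * a$mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    ci_single <- c(
      n * (a$msb - f_l * a$mse) /
        (f_l * (k * a$msc + (k * n - k - n) * a$mse) + n * a$msb),
      n * (f_u * a$msb - a$mse) /
        (k * a$msc + (k * n - k - n) * a$mse + n * f_u * a$msb))
    label <- "two-way random, ICC(2,1)/ICC(2,k)"
  }
  sb <- function(s) k * s / (1 + (k - 1) * s)
  structure(
    list(single = single, average = sb(single),
         ci_single = pmin(pmax(ci_single, -1), 1),
         ci_average = pmin(pmax(sb(ci_single), -1), 1),
         model_label = label, n_subjects = n, k_repeats = k, flags = flags),
    class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat("Intraclass correlation (", x$model_label, ")\n", sep = "")
  cat(sprintf("  single:  %.3f (95%% CI %.3f-%.3f)\n",
              x$single, x$ci_single[1], x$ci_single[2]))
  cat(sprintf("  average: %.3f (95%% CI %.3f-%.3f)  [n = %d, k = %d]\n",
              x$average, x$ci_average[1], x$ci_average[2],
              x$n_subjects, x$k_repeats))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
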
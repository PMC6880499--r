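# Fixtures and independent oracles used across the suite.

# Build a recovery segment directly (bypassing trace segmentation) from a
# relative time grid and intensities.
make_segment <- function(rel_times, intensities, baseline = NULL,
                         sampling_interval = NULL) {
  structure(
    list(t_release = 0,
         rel_times = rel_times,
         intensities = intensities,
         baseline = baseline %||% min(intensities),
         release_level = intensities[1],
         sampling_interval = sampling_interval %||% diff(rel_times[1:2]),
         polarity_ok = intensities[1] >= (baseline %||% min(intensities))),
    class = "recovery_segment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exponential recovery samples: B + A * exp(-t / tau).
exp_segment <- function(tau, A = 100, B = 500, dt = 0.016, dur = 15,
                        noise_sd = 0) {
  t <- seq(0, dur, by = dt)
  y <- B + A * exp(-t / tau)
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  make_segment(t, y, baseline = B)
}

# AUC by brute-force pair counting: concordant pairs plus half the ties
# over all positive-negative pairs.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# One-way ICC from explicit ANOVA sums, written independently of the
# package internals (double loops, no matrix shortcuts).
icc_oneway_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ssb <- 0
  for (i in seq_len(n)) {
    rm_i <- sum(m[i, ]) / k
    ssb <- ssb + k * (rm_i - grand)^2
  }
  ssw <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    rm_i <- sum(m[i, ]) / k
    ssw <- ssw + (m[i, j] - rm_i)^2
  }
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

# Two-way ICC(2,1) from explicit sums (Shrout-Fleiss).
icc_twoway_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ssb <- ssc <- sst <- 0
  for (i in seq_len(n)) ssb <- ssb + k * (sum(m[i, ]) / k - grand)^2
  for (j in seq_len(k)) ssc <- ssc + n * (sum(m[, j]) / n - grand)^2
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (m[i, j] - grand)^2
  sse <- sst - ssb - ssc
  msb <- ssb / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msb - mse) / (msb + (k - 1) * mse + k * (msc - mse) / n)
}

# Exhaustive tau grid search oracle for the exponential fit: at each of
# `n_grid` taus, solve the linear subproblem with lm() and record the rss.
grid_fit_oracle <- function(t, y, bounds = c(0.05, 60), n_grid = 10000) {
  taus <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_grid))
  best <- Inf; best_tau <- NA
  for (tau in taus) {
    x <- exp(-t / tau)
    fit <- stats::lm(y ~ x)
    rss <- sum(stats::resid(fit)^2)
    if (rss < best) { best <- rss; best_tau <- tau }
  }
  list(tau = best_tau, rss = best)
}

# Vectorised version of the same oracle (used where 10,000-point grids on
# many segments would otherwise dominate runtime): same grid, closed-form
# simple-regression algebra written out directly.
grid_fit_oracle_fast <- function(t, y, bounds = c(0.05, 60), n_grid = 10000) {
  taus <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_grid))
  n <- length(y)
  rss <- vapply(taus, function(tau) {
    x <- exp(-t / tau)
    mx <- mean(x); my <- mean(y)
    sxx <- sum((x - mx)^2)
    if (sxx < .Machine$double.eps) return(sum((y - my)^2))
    b1 <- sum((x - mx) * (y - my)) / sxx
    sum((y - (my + b1 * (x - mx)))^2)
  }, numeric(1))
  k <- which.min(rss)
  list(tau = taus[k], rss = rss[k])
}
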
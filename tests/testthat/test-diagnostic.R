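test_that("roc_curve reproduces canonical AUC values", {
  expect_equal(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  # 3 concordant of 4 positive-negative pairs
  expect_equal(roc_curve(c(3, 1, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  # all ties: chance performance
  expect_equal(roc_curve(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("ROC points are monotone and their trapezoidal area is the AUC", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    scores <- sample(round(rnorm(n), 1))  # induce ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    roc <- roc_curve(scores, labels)
    pts <- roc$points
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$tpr) >= 0))
    expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
    expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
    trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
    expect_equal(roc$auc, trap, tolerance = 1e-12)
  }
})

test_that("AUC equals brute-force pair counting on random inputs", {
  set.seed(8)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    scores <- round(rnorm(n), sample(0:2, 1))
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(roc_curve(scores, labels)$auc, brute_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC respects direction reversal and monotone transforms", {
  set.seed(5)
  scores <- rnorm(30); labels <- rbinom(30, 1, 0.4)
  labels[1:2] <- c(0, 1)
  a <- roc_curve(scores, labels)$auc
  expect_equal(roc_curve(scores, labels, "less")$auc, 1 - a, tolerance = 1e-12)
  expect_equal(roc_curve(exp(scores), labels)$auc, a, tolerance = 1e-12)
  expect_equal(roc_curve(scores^3, labels)$auc, a, tolerance = 1e-12)
})

test_that("DeLong interval is sane and tightens with sample size", {
  set.seed(6)
  mk <- function(n) {
    labels <- rep(0:1, each = n)
    scores <- rnorm(2 * n, mean = labels)
    roc_curve(scores, labels)
  }
  small <- mk(20); big <- mk(500)
  for (r in list(small, big)) {
    expect_gte(r$auc_ci[1], 0); expect_lte(r$auc_ci[2], 1)
    expect_gte(r$auc, r$auc_ci[1]); expect_lte(r$auc, r$auc_ci[2])
  }
  expect_lt(diff(big$auc_ci), diff(small$auc_ci))
})

test_that("the left-upper-corner cutoff lands between straddling scores", {
  sc <- c(1, 2, 3, 4); lb <- c(0, 0, 1, 1)
  expect_equal(optimal_cutoff(roc_curve(sc, lb), sc, lb), 2.5)

  # all four operating points enumerated by hand: (0,1) wins at threshold 1
  sc2 <- c(1, 2, 3); lb2 <- c(0, 1, 1)
  expect_equal(optimal_cutoff(roc_curve(sc2, lb2), sc2, lb2), 1.5)

  # degenerate all-tied scores: warn, fall back to the tie rule
  sc3 <- rep(2, 4); lb3 <- c(0, 1, 0, 1)
  expect_warning(ct <- optimal_cutoff(roc_curve(sc3, lb3), sc3, lb3),
                 "degenerate")
  expect_true(is.finite(ct))
})

test_that("confusion_at reproduces the published 2x2 exactly", {
  # 12 admitted (10 above the cutoff), 18 discharged (7 above)
  scores <- c(rep(3.0, 10), rep(2.0, 2), rep(3.0, 7), rep(2.0, 11))
  labels <- c(rep(1, 12), rep(0, 18))
  tab <- confusion_at(scores, labels, cutoff = 2.74)
  expect_equal(c(tab$tp, tab$fp, tab$fn, tab$tn), c(10, 7, 2, 11))
  expect_equal(unname(tab$display),
               c(83.3, 61.1, 58.8, 84.6))
})

test_that("confusion_at honours strict-greater positivity and edge cases", {
  tab <- confusion_at(c(1, 2, 3, 4), c(0, 0, 1, 1), cutoff = 2)
  expect_equal(unname(tab$display), c(100, 100, 100, 100))

  # boundary value is negative under the strict rule, positive under ge
  strict <- confusion_at(c(2, 3), c(1, 1), cutoff = 2)
  expect_equal(strict$tp, 1)
  ge <- confusion_at(c(2, 3), c(1, 1), cutoff = 2, positive_if = "ge")
  expect_equal(ge$tp, 2)

  # cutoff above all scores: forced negative corner
  hi <- confusion_at(c(1, 2, 3), c(1, 0, 0), cutoff = 10)
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 100)
  expect_equal(hi$npv, 100 * 2 / 3, tolerance = 1e-12)

  expect_error(confusion_at(numeric(0), numeric(0), 1), "empty")
})

test_that("complement identities hold for the 2x2 metrics", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(6:40, 1)
    scores <- rnorm(n); labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    tab <- confusion_at(scores, labels, cutoff = median(scores))
    fnr <- 100 * tab$fn / (tab$tp + tab$fn)
    fpr <- 100 * tab$fp / (tab$tn + tab$fp)
    expect_equal(tab$sensitivity + fnr, 100, tolerance = 1e-12)
    expect_equal(tab$specificity + fpr, 100, tolerance = 1e-12)
  }
})

test_that("percent coefficient of variation matches the published roundings", {
  expect_equal(cv_percent(2.35, 0.97)$display, 41)
  expect_equal(cv_percent(4.69, 3.14)$display, 67)
  expect_equal(cv_percent(3.35, 2.23)$display, 67)
  expect_equal(cv_percent(5, 0)$exact, 0)
  expect_error(cv_percent(0, 1), "positive")
})

test_that("abnormal-CRT flag applies the strict 3-s rule", {
  expect_true(crt_abnormal_flag(4.44))
  expect_false(crt_abnormal_flag(3.0))
  expect_false(crt_abnormal_flag(1.24))
  expect_identical(crt_abnormal_flag(c(2, 3.5), cutoff = 3), c(FALSE, TRUE))
})
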
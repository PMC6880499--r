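test_that("pearson_r matches hand computation and the stats oracle", {
  expect_equal(pearson_r(1:5, 1:5)$r, 1)
  expect_equal(pearson_r(1:5, -(1:5))$r, -1)
  # hand-computed product-moment value
  res <- pearson_r(c(1, 2, 3), c(1, 2, 4))
  expect_equal(res$r, 9 / sqrt(84), tolerance = 1e-12)

  set.seed(4)
  x <- rnorm(25); y <- 0.6 * x + rnorm(25)
  ref <- cor.test(x, y)
  mine <- pearson_r(x, y)
  expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(1:4, 1:5), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("pearson_r is invariant under positive affine transforms", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(20)
    r0 <- pearson_r(x, y)$r
    expect_equal(pearson_r(2.5 * x + 7, y)$r, r0, tolerance = 1e-12)
    expect_equal(pearson_r(x, 0.3 * y - 2)$r, r0, tolerance = 1e-12)
  }
})

test_that("bland_altman reproduces closed-form toy cases", {
  ident <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$bias, 0)
  expect_equal(ident$sd_diff, 0)
  expect_equal(ident$prop_slope, 0)

  off <- bland_altman(c(2, 3, 4), c(1, 2, 3))
  expect_equal(off$bias, 1)
  expect_equal(off$sd_diff, 0)
  expect_equal(off$loa_lower, 1)
  expect_equal(off$loa_upper, 1)

  # a = 2b: differences (1,2,3) on averages (1.5,3,4.5) -> OLS slope 2/3
  prop <- bland_altman(c(2, 4, 6), c(1, 2, 3))
  expect_equal(prop$prop_slope, 2 / 3, tolerance = 1e-12)

  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("swapping methods flips the Bland-Altman analysis sign", {
  set.seed(7)
  a <- rlnorm(20, 1, 0.4); b <- rlnorm(20, 0.6, 0.3)
  ab <- bland_altman(a, b); ba <- bland_altman(b, a)
  expect_equal(ab$bias, -ba$bias, tolerance = 1e-12)
  expect_equal(ab$loa_lower, -ba$loa_upper, tolerance = 1e-12)
  expect_equal(ab$loa_upper, -ba$loa_lower, tolerance = 1e-12)
  expect_equal(ab$prop_slope, -ba$prop_slope, tolerance = 1e-12)
})

test_that("icc matches the hand-ANOVA value on the toy matrix", {
  m <- matrix(1:12, nrow = 4, ncol = 3, byrow = TRUE)
  # MSB = 45, MSW = 1 by explicit ANOVA sums => ICC(1,1) = 44/47
  res <- icc(m)
  expect_equal(res$single, 44 / 47, tolerance = 1e-12)
  expect_equal(res$average, 3 * (44 / 47) / (1 + 2 * 44 / 47), tolerance = 1e-12)
})

test_that("icc handles the degenerate variance structures", {
  # repeats identical, subjects differ: perfect reliability
  m <- matrix(rep(c(1, 5, 9, 13), 3), ncol = 3)
  res <- icc(m)
  expect_equal(res$single, 1)
  expect_equal(res$average, 1)

  # subjects identical: no between-subject variance to detect
  m2 <- matrix(rep(c(1, 2, 3), each = 4), ncol = 3)
  res2 <- icc(m2)
  expect_lte(res2$single, 0)
  expect_true("no_between_subject_variance" %in% res2$flags)

  expect_error(icc(matrix(c(1, NA, 3, 4), 2, 2)), "incomplete")
  expect_error(icc(matrix(1:3, 1, 3)), ">= 2 subjects")
})

test_that("Spearman-Brown links single and average ICC exactly", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(4:10, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, rep(rnorm(n, sd = 2), k)), n, k)
    for (mod in c("oneway", "twoway_random")) {
      res <- icc(m, model = mod)
      s <- res$single
      expect_equal(res$average, k * s / (1 + (k - 1) * s), tolerance = 1e-12)
    }
  }
})

test_that("icc equals brute-force ANOVA sums on random small matrices", {
  set.seed(33)
  for (i in 1:100) {
    n <- sample(3:10, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, rep(rnorm(n, sd = 1.5), k)), n, k)
    expect_equal(icc(m, "oneway")$single, icc_oneway_oracle(m),
                 tolerance = 1e-10)
    expect_equal(icc(m, "twoway_random")$single, icc_twoway_oracle(m),
                 tolerance = 1e-10)
  }
})

test_that("ICC confidence intervals bracket the estimate and behave at the edges", {
  set.seed(14)
  m <- matrix(rnorm(30, rep(rnorm(10, sd = 3), 3), sd = 0.5), 10, 3)
  for (mod in c("oneway", "twoway_random")) {
    res <- icc(m, model = mod)
    expect_lte(res$ci_single[1], res$single)
    expect_gte(res$ci_single[2], res$single)
    expect_lte(res$ci_average[1], res$average)
    expect_gte(res$ci_average[2], res$average)
  }
})

test_that("reliability falls as within-subject noise grows", {
  singles <- vapply(c(0.02, 0.15, 0.5), function(cv) {
    coh <- simulate_cohort(within_subject_cv = cv, seed = 21)
    icc(coh[, paste0("crt", 1:3)])$single
  }, numeric(1))
  expect_true(all(diff(singles) < 0))
  coh0 <- simulate_cohort(within_subject_cv = 0, seed = 21)
  expect_equal(icc(coh0[, paste0("crt", 1:3)])$single, 1, tolerance = 1e-9)
})
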
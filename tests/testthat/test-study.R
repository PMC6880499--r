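test_that("temperature gradients match the published worked values", {
  # Table-level cohort means: fingertip 27.8, forearm 32.5, body 37.0 degC
  tg <- temp_gradients(27.8, 32.5, 37.0)
  expect_equal(tg$tskin_diff, -4.7)
  expect_equal(tg$tc_diff, -9.2)
  expect_equal(temp_gradients(30, 30, 30), data.frame(tskin_diff = 0, tc_diff = 0))
  expect_warning(temp_gradients(10, 32, 37), "physiological")
  miss <- temp_gradients(c(28, NA), c(32, 33), c(37, 38))
  expect_true(is.na(miss$tskin_diff[2]))
})

test_that("run_study completes on a simulated cohort with the built-in bias", {
  rep <- run_study(simulate_cohort(seed = 42))
  expect_s3_class(rep, "study_report")
  # BRT reads longer than CRT by construction: positive Bland-Altman bias
  expect_gt(rep$bland_altman$bias, 0)
  expect_gt(rep$correlation$r, 0)
  expect_true(is.finite(rep$roc_admission_brt$auc))
  expect_true(is.finite(rep$optimal_cutoff_brt))
  expect_length(rep$crt_mean, 30)
  # covariate correlations carry their per-variable n
  expect_true(all(vapply(rep$covariates, function(cv) cv$n >= 3, logical(1))))
})

test_that("run_study enforces its preconditions and degrades gracefully", {
  expect_error(run_study(simulate_cohort(n_subjects = 4, seed = 1)),
               "at least 5")
  coh <- simulate_cohort(seed = 3)
  coh$admitted <- 0L  # single-outcome cohort
  expect_warning(rep <- run_study(coh), "ROC stages skipped")
  expect_null(rep$roc_admission_brt)
  expect_s3_class(rep$bland_altman, "bland_altman")  # remainder computed
})

test_that("zero within-subject noise drives both ICC singles to 1", {
  rep <- run_study(simulate_cohort(within_subject_cv = 0, seed = 11))
  expect_equal(rep$icc_crt$single, 1, tolerance = 1e-9)
  expect_equal(rep$icc_brt$single, 1, tolerance = 1e-9)
})

test_that("the reported 2x2 re-derives exactly from the cohort scores", {
  rep <- run_study(simulate_cohort(seed = 5))
  redo <- confusion_at(rep$brt_mean,
                       as.data.frame(simulate_cohort(seed = 5))$admitted,
                       rep$optimal_cutoff_brt)
  d <- rep$diagnostics_brt
  expect_identical(c(d$tp, d$fp, d$fn, d$tn),
                   c(redo$tp, redo$fp, redo$fn, redo$tn))
})

test_that("identical inputs give byte-identical JSON reports", {
  p1 <- file.path(tempdir(), "rep1.json")
  p2 <- file.path(tempdir(), "rep2.json")
  write_study_json(run_study(simulate_cohort(seed = 99)), p1)
  write_study_json(run_study(simulate_cohort(seed = 99)), p2)
  expect_identical(readLines(p1), readLines(p2))
  file.remove(p1, p2)
})

test_that("waveform batches isolate per-trial failures", {
  dir <- file.path(tempdir(), "batch")
  dir.create(dir, showWarnings = FALSE)
  paths <- character(0)
  for (i in 1:3) {
    sim <- simulate_waveform(tau = 1 + i / 2, seed = 100 + i,
                             trial_id = paste0("T", i))
    p <- file.path(dir, sprintf("trial%d.csv", i))
    write_waveform_csv(sim$trace, p)
    paths <- c(paths, p)
  }
  bad <- file.path(dir, "corrupt.csv")
  writeLines("this,is\nnot,a waveform", bad)

  res <- process_waveform_batch(c(paths, bad))
  expect_equal(nrow(res), 4)
  expect_true(all(is.finite(res$brt[1:3])))
  expect_true(is.na(res$brt[4]) && !is.na(res$error[4]))
  # triplicate mean agrees with average_repeats on the same values
  expect_equal(mean(res$brt[1:3]), average_repeats(res$brt[1:3]))

  expect_warning(empty <- process_waveform_batch(character(0)), "empty")
  expect_equal(nrow(empty), 0)
  unlink(dir, recursive = TRUE)
})

test_that("measure_brt surfaces staged errors and tolerates noisy defaults", {
  t <- seq(0, 20, by = 0.016)
  flat <- ppg_trace(t, rep(500, length(t)))
  expect_error(measure_brt(flat), "stage detect")

  # true tau 1.5 with default pulsation and noise: within 10% of tau*ln10
  sim <- simulate_waveform(tau = 1.5, seed = 77)
  m <- measure_brt(sim$trace)
  expect_lt(abs(brt(m) - sim$ground_truth_brt) / sim$ground_truth_brt, 0.10)
})

test_that("brt_fit behaves like a fitted model object", {
  sim <- simulate_waveform(tau = 2, seed = 13)
  m <- measure_brt(sim$trace)
  expect_named(coef(m), c("A", "tau", "B"))
  expect_equal(length(residuals(m)), m$fit$n_points)
  expect_equal(predict(m, times = 0), m$fit$A + m$fit$B, tolerance = 1e-9)
  expect_output(print(m), "BRT")
  expect_output(print(summary(m)), "quality")
  sims <- simulate(m, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "ppg_trace")
})
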
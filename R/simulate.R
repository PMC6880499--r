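# Synthetic data: compression-release PPG waveforms with known ground-truth
# refill time, and paired-method cohorts emulating the study's structure.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate a compression-release PPG waveform
#'
#' Builds a transmitted-light intensity trace: constant baseline plus linear
#' drift, a compression profile (linear ramp over `ramp_time` to
#' `baseline + amplitude`, plateau for `compression_duration`, then
#' exponential recovery `amplitude * exp(-t/tau)` after release), a cardiac
#' pulsation sinusoid, and additive Gaussian noise. The ground-truth blood
#' refill time is `tau * log(10)` (time to 90% return on the noise-free
#' recovery).
#'
#' Default noise levels model a clean bedside recording: pulsatile ripple 5%
#' of the compression amplitude, white noise 1%, and a slow drift of
#' 0.2 units/s.
#'
#' @param tau Recovery time constant, seconds.
#' @param baseline Pre-compression intensity, device units (default 500).
#' @param amplitude Intensity rise under compression (default 100).
#' @param compression_onset Compression start time, seconds (default 5).
#' @param compression_duration Compression length, seconds (default 5).
#' @param ramp_time Linear rise time to the plateau, seconds (default 0.3).
#' @param pulse_amplitude Cardiac pulsation amplitude (default 5).
#' @param heart_rate Beats per minute (default 75).
#' @param drift_slope Baseline drift, units per second (default 0.2).
#' @param noise_sd Gaussian noise SD, device units (default 1).
#' @param total_duration Trace length, seconds (default 30).
#' @param sampling_interval Seconds per sample (default 0.016).
#' @param seed Integer seed; identical seeds give bit-identical traces.
#' @param trial_id Label carried into the trace.
#' @param markers Attach the true start/release times as a
#'   [compression_protocol()] attribute (default `TRUE`, emulating the
#'   device's beep markers). Set `FALSE` to exercise auto-detection.
#' @return List with `trace` (a [ppg_trace()]), `ground_truth_brt`
#'   (seconds), `t_start`, `t_release`, and `params`.
#' @examples
#' sim <- simulate_waveform(tau = 2, noise_sd = 0, pulse_amplitude = 0,
#'                          drift_slope = 0)
#' sim$ground_truth_brt   # 2 * log(10) = 4.60517
#' @export
simulate_waveform <- function(tau, baseline = 500, amplitude = 100,
                              compression_onset = 5,
                              compression_duration = 5, ramp_time = 0.3,
                              pulse_amplitude = 5, heart_rate = 75,
                              drift_slope = 0.2, noise_sd = 1,
                              total_duration = 30,
                              sampling_interval = 0.016, seed = NULL,
                              trial_id = NULL, markers = TRUE) {
  if (tau <= 0) stop("`tau` must be positive")
  if (amplitude < 0) stop("`amplitude` must be non-negative")
  if (compression_duration <= 0 || total_duration <= 0 || sampling_interval <= 0)
    stop("durations and sampling interval must be positive")
  t_release <- compression_onset + compression_duration
  if (total_duration < t_release + 5 * tau)
    warning("trace ends before ~5 time constants of recovery; fits may be poor")

  tt <- seq(0, total_duration, by = sampling_interval)
  comp <- numeric(length(tt))
  ramp <- tt >= compression_onset & tt < compression_onset + ramp_time
  comp[ramp] <- amplitude * (tt[ramp] - compression_onset) / ramp_time
  plateau <- tt >= compression_onset + ramp_time & tt < t_release
  comp[plateau] <- amplitude
  rec <- tt >= t_release
  comp[rec] <- amplitude * exp(-(tt[rec] - t_release) / tau)

  pulse <- pulse_amplitude * sin(2 * pi * heart_rate / 60 * tt)
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(tt), 0, noise_sd))
  } else numeric(length(tt))

  intensity <- pmax(0, baseline + drift_slope * tt + comp + pulse + noise)
  tr <- ppg_trace(tt, intensity, sampling_interval = sampling_interval,
                  trial_id = trial_id)
  if (markers) {
    attr(tr, "protocol") <- compression_protocol(
      compression_duration = compression_duration,
      t_start = compression_onset, t_release = t_release)
  }
  list(trace = tr, ground_truth_brt = tau * log(10),
       t_start = compression_onset, t_release = t_release,
       params = list(tau = tau, baseline = baseline, amplitude = amplitude,
                     compression_onset = compression_onset,
                     compression_duration = compression_duration,
                     ramp_time = ramp_time, pulse_amplitude = pulse_amplitude,
                     heart_rate = heart_rate, drift_slope = drift_slope,
                     noise_sd = noise_sd, total_duration = total_duration,
                     sampling_interval = sampling_interval, seed = seed))
}

# Lognormal parameters from a natural-scale mean and SD.
lnorm_params <- function(m, s) {
  if (m <= 0 || s <= 0) stop("lognormal calibration needs positive mean and SD")
  sigma2 <- log(1 + (s / m)^2)
  list(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}

# Log-scale correlation that yields natural-scale correlation r for a
# bivariate lognormal with log-scale SDs s1, s2.
lnorm_rho <- function(r, s1, s2) {
  arg <- 1 + r * sqrt(expm1(s1^2) * expm1(s2^2))
  if (arg <= 0) stop("calibration error: correlation ", r, " infeasible for these moments")
  rho <- log(arg) / (s1 * s2)
  if (abs(rho) > 1) stop("calibration error: correlation ", r, " infeasible for these moments")
  rho
}

#' Simulate a paired-method refill-time cohort
#'
#' Emulates a 30-subject emergency-department cohort measured in triplicate
#' by two methods: standardized visual capillary refill time (CRT, judged
#' with a chronometer) and device blood refill time (BRT). Admission status
#' is Bernoulli; per-subject true (CRT, BRT) pairs are drawn from a
#' bivariate lognormal calibrated so each group's natural-scale means/SDs
#' match the requested values and the cross-method correlation matches
#' `target_correlation`; triplicates multiply the true value by lognormal
#' within-subject noise with coefficient of variation `within_subject_cv`.
#' Refill times are therefore positive and right-skewed, and BRT reads
#' systematically longer than CRT with a larger spread (a built-in
#' proportional bias). Default group moments follow the published cohort.
#'
#' Temperature covariates (fingertip, forearm, body) are drawn around the
#' published cohort means/SDs and support the skin/core temperature-gradient
#' derivations.
#'
#' @param n_subjects Number of subjects (default 30).
#' @param admit_rate Admission probability (default 0.4).
#' @param crt_admitted,crt_discharged,brt_admitted,brt_discharged Numeric
#'   `c(mean, sd)` pairs in seconds for each method/group (defaults
#'   2.35/0.97, 1.65/0.47, 4.69/3.14, 3.35/2.23).
#' @param target_correlation Natural-scale CRT-BRT Pearson correlation of
#'   the true values within each group (default 0.72).
#' @param within_subject_cv Coefficient of variation of the triplicate
#'   noise (default 0.15; 0 gives identical repeats and ICC of 1).
#' @param seed Integer seed; output is deterministic per seed.
#' @return A `data.frame` of class `refill_cohort` with columns
#'   `subject_id`, `admitted`, `crt1..3`, `brt1..3`, `crt_mean`,
#'   `brt_mean`, `fingertip_temp`, `forearm_temp`, `body_temp`.
#' @examples
#' coh <- simulate_cohort(seed = 1)
#' head(coh[, c("subject_id", "admitted", "crt_mean", "brt_mean")])
#' @export
simulate_cohort <- function(n_subjects = 30, admit_rate = 0.4,
                            crt_admitted = c(2.35, 0.97),
                            crt_discharged = c(1.65, 0.47),
                            brt_admitted = c(4.69, 3.14),
                            brt_discharged = c(3.35, 2.23),
                            target_correlation = 0.72,
                            within_subject_cv = 0.15, seed = NULL) {
  if (admit_rate <= 0 || admit_rate >= 1) stop("`admit_rate` must lie in (0, 1)")
  if (abs(target_correlation) >= 1) stop("`target_correlation` must lie in (-1, 1)")
  if (within_subject_cv < 0) stop("`within_subject_cv` must be non-negative")

  groups <- list(
    admitted = list(crt = lnorm_params(crt_admitted[1], crt_admitted[2]),
                    brt = lnorm_params(brt_admitted[1], brt_admitted[2])),
    discharged = list(crt = lnorm_params(crt_discharged[1], crt_discharged[2]),
                      brt = lnorm_params(brt_discharged[1], brt_discharged[2])))
  for (g in names(groups))
    groups[[g]]$rho <- lnorm_rho(target_correlation,
                                 groups[[g]]$crt$sigma, groups[[g]]$brt$sigma)

  sw <- sqrt(log(1 + within_subject_cv^2))

  with_seed(seed, {
    admitted <- stats::rbinom(n_subjects, 1, admit_rate)
    crt_true <- brt_true <- numeric(n_subjects)
    for (i in seq_len(n_subjects)) {
      g <- groups[[if (admitted[i] == 1) "admitted" else "discharged"]]
      z1 <- stats::rnorm(1)
      z2 <- g$rho * z1 + sqrt(1 - g$rho^2) * stats::rnorm(1)
      crt_true[i] <- exp(g$crt$mu + g$crt$sigma * z1)
      brt_true[i] <- exp(g$brt$mu + g$brt$sigma * z2)
    }
    reps <- function(true) {
      e <- matrix(stats::rnorm(3 * n_subjects, -sw^2 / 2, sw), ncol = 3)
      true * exp(e)
    }
    crt <- reps(crt_true)
    brt <- reps(brt_true)
    clamp <- function(x) pmin(pmax(x, 15), 45)
    out <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n_subjects)),
      admitted = admitted,
      crt1 = crt[, 1], crt2 = crt[, 2], crt3 = crt[, 3],
      brt1 = brt[, 1], brt2 = brt[, 2], brt3 = brt[, 3],
      fingertip_temp = clamp(stats::rnorm(n_subjects, 27.8, 3.0)),
      forearm_temp = clamp(stats::rnorm(n_subjects, 32.5, 1.0)),
      body_temp = clamp(stats::rnorm(n_subjects, 37.0, 0.5)))
    out$crt_mean <- rowMeans(crt)
    out$brt_mean <- rowMeans(brt)
    attr(out, "params") <- list(
      n_subjects = n_subjects, admit_rate = admit_rate,
      target_correlation = target_correlation,
      within_subject_cv = within_subject_cv, seed = seed)
    class(out) <- c("refill_cohort", "data.frame")
    out
  })
}

#' Read / write a cohort CSV
#'
#' The cohort file is a plain CSV with columns `subject_id`, `admitted`
#' (0/1), `crt1..crt3`, `brt1..brt3`, and optional temperature columns
#' `fingertip_temp`, `forearm_temp`, `body_temp`. Per-subject means are
#' recomputed on read as the arithmetic mean of the triplicates.
#'
#' @param path CSV path.
#' @return `read_cohort_csv`: a `refill_cohort` data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject_id", "admitted", paste0("crt", 1:3), paste0("brt", 1:3))
  if (!all(need %in% names(df)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  df$crt_mean <- rowMeans(df[, paste0("crt", 1:3)])
  df$brt_mean <- rowMeans(df[, paste0("brt", 1:3)])
  class(df) <- c("refill_cohort", "data.frame")
  df
}

#' @rdname read_cohort_csv
#' @param cohort A `refill_cohort` data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- intersect(c("subject_id", "admitted", paste0("crt", 1:3),
                      paste0("brt", 1:3), "fingertip_temp", "forearm_temp",
                      "body_temp"), names(cohort))
  utils::write.csv(as.data.frame(cohort)[, cols], path, row.names = FALSE)
  invisible(path)
}
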
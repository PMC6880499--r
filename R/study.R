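# Whole-study orchestration: covariate derivations, the paired-method
# comparison report, and batch waveform processing.

#' Skin and core temperature gradients
#'
#' Objective perfusion surrogates: `tskin_diff` is fingertip minus forearm
#' surface temperature and `tc_diff` is fingertip minus body (core)
#' temperature, both in degrees Celsius. A poorly perfused fingertip is
#' cooler than the forearm and core, so both gradients go negative.
#'
#' @param fingertip,forearm,body Temperatures in degrees C (vectors
#'   recycle); `NA` propagates.
#' @return Data frame with columns `tskin_diff`, `tc_diff`.
#' @examples
#' temp_gradients(27.8, 32.5, 37.0)  # -4.7, -9.2
#' @export
temp_gradients <- function(fingertip, forearm = NULL, body = NULL) {
  chk <- function(x, nm) {
    if (!is.null(x) && any(!is.na(x) & (x < 15 | x > 45)))
      warning(nm, " outside the physiological 15-45 degC range")
    x
  }
  chk(fingertip, "fingertip"); chk(forearm, "forearm"); chk(body, "body")
  data.frame(
    tskin_diff = if (is.null(forearm)) NA_real_ else fingertip - forearm,
    tc_diff = if (is.null(body)) NA_real_ else fingertip - body)
}

#' Run the full paired-method comparison analysis
#'
#' Reproduces the study's statistical pipeline on a cohort of triplicate
#' CRT/BRT measurements: per-subject means ([average_repeats()]), the
#' CRT-BRT Pearson correlation, Bland-Altman agreement, per-method
#' intraclass correlation, ROC of BRT against abnormal CRT (> `crt_cutoff`),
#' ROC with left-upper-corner optimal cutoff and 2x2 diagnostics for
#' admission by each method, percent coefficients of variation by group, and
#' correlations of each method with available covariates (pairwise-complete;
#' per-variable n reported).
#'
#' @param cohort A `refill_cohort` data frame ([simulate_cohort()],
#'   [read_cohort_csv()]); >= 5 subjects.
#' @param crt_cutoff Abnormal-CRT threshold in seconds (default 3).
#' @param icc_model ICC model passed to [icc()] (default one-way random).
#' @return Object of class `study_report` with elements `summary` (group
#'   means/SDs and %CV), `correlation`, `bland_altman`, `icc_crt`,
#'   `icc_brt`, `roc_brt_vs_crt`, `roc_admission_brt`, `roc_admission_crt`,
#'   `optimal_cutoff_brt`, `diagnostics_brt`, `covariates`, `n_subjects`.
#' @examples
#' rep <- run_study(simulate_cohort(seed = 42))
#' print(rep)
#' @export
run_study <- function(cohort, crt_cutoff = 3.0,
                      icc_model = c("oneway", "twoway_random")) {
  icc_model <- match.arg(icc_model)
  df <- as.data.frame(cohort)
  if (nrow(df) < 5L) stop("need at least 5 subjects")
  crt_rep <- as.matrix(df[, paste0("crt", 1:3)])
  brt_rep <- as.matrix(df[, paste0("brt", 1:3)])
  crt_mean <- apply(crt_rep, 1, average_repeats)
  brt_mean <- apply(brt_rep, 1, average_repeats)

  group_stats <- function(x, g) {
    s <- function(v) {
      cv <- if (mean(v) > 0) cv_percent(mean(v), stats::sd(v)) else
        list(exact = NA_real_, display = NA_real_)
      c(n = length(v), mean = mean(v), sd = stats::sd(v),
        cv_exact = cv$exact, cv_display = cv$display)
    }
    rbind(admitted = s(x[g == 1]), discharged = s(x[g == 0]),
          overall = s(x))
  }

  have_outcome <- "admitted" %in% names(df) &&
    length(unique(df$admitted)) == 2L

  corr <- pearson_r(crt_mean, brt_mean)
  ba <- bland_altman(brt_mean, crt_mean)  # differences = BRT - CRT
  icc_crt <- icc(crt_rep, model = icc_model)
  icc_brt <- icc(brt_rep, model = icc_model)

  abnormal_crt <- as.integer(crt_abnormal_flag(crt_mean, crt_cutoff))
  roc_brt_vs_crt <- if (length(unique(abnormal_crt)) == 2L)
    roc_curve(brt_mean, abnormal_crt) else NULL

  roc_adm_brt <- roc_adm_crt <- cut_brt <- diag_brt <- NULL
  if (have_outcome) {
    roc_adm_brt <- roc_curve(brt_mean, df$admitted)
    roc_adm_crt <- roc_curve(crt_mean, df$admitted)
    cut_brt <- optimal_cutoff(roc_adm_brt, brt_mean, df$admitted)
    diag_brt <- confusion_at(brt_mean, df$admitted, cut_brt)
  } else {
    warning("single-outcome cohort: admission ROC stages skipped")
  }

  cov_names <- intersect(c("fingertip_temp", "forearm_temp", "body_temp",
                           "tskin_diff", "tc_diff"), names(df))
  if (all(c("fingertip_temp", "forearm_temp", "body_temp") %in% names(df))) {
    tg <- temp_gradients(df$fingertip_temp, df$forearm_temp, df$body_temp)
    df$tskin_diff <- tg$tskin_diff
    df$tc_diff <- tg$tc_diff
    cov_names <- union(cov_names, c("tskin_diff", "tc_diff"))
  }
  covariates <- lapply(cov_names, function(v) {
    ok <- !is.na(df[[v]])
    if (sum(ok) < 3L || stats::sd(df[[v]][ok]) == 0) return(NULL)
    list(variable = v, n = sum(ok),
         crt = pearson_r(crt_mean[ok], df[[v]][ok]),
         brt = pearson_r(brt_mean[ok], df[[v]][ok]))
  })
  covariates <- covariates[!vapply(covariates, is.null, logical(1))]

  structure(
    list(n_subjects = nrow(df),
         admit_rate = if (have_outcome) mean(df$admitted) else NA_real_,
         summary = list(
           crt = if (have_outcome) group_stats(crt_mean, df$admitted) else NULL,
           brt = if (have_outcome) group_stats(brt_mean, df$admitted) else NULL),
         crt_mean = crt_mean, brt_mean = brt_mean,
         correlation = corr, bland_altman = ba,
         icc_crt = icc_crt, icc_brt = icc_brt,
         roc_brt_vs_crt = roc_brt_vs_crt,
         roc_admission_brt = roc_adm_brt, roc_admission_crt = roc_adm_crt,
         optimal_cutoff_brt = cut_brt, diagnostics_brt = diag_brt,
         covariates = covariates, crt_cutoff = crt_cutoff),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Refill-time method comparison (n = %d subjects)\n", x$n_subjects))
  if (!is.na(x$admit_rate))
    cat(sprintf("  admission rate: %.0f%%\n", 100 * x$admit_rate))
  cat(sprintf("  CRT-BRT Pearson r = %.3f (p = %.3g)\n",
              x$correlation$r, x$correlation$p))
  cat(sprintf("  Bland-Altman bias (BRT - CRT) = %.3f s, LoA [%.2f, %.2f]\n",
              x$bland_altman$bias, x$bland_altman$loa_lower,
              x$bland_altman$loa_upper))
  cat(sprintf("  ICC single: CRT %.3f, BRT %.3f\n",
              x$icc_crt$single, x$icc_brt$single))
  if (!is.null(x$roc_admission_brt)) {
    cat(sprintf("  admission AUC: BRT %.3f, CRT %.3f; BRT cutoff %.2f s\n",
                x$roc_admission_brt$auc, x$roc_admission_crt$auc,
                x$optimal_cutoff_brt))
    d <- x$diagnostics_brt$display
    cat(sprintf("  at cutoff: sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%%\n",
                d["sensitivity"], d["specificity"], d["ppv"], d["npv"]))
  }
  invisible(x)
}

#' Serialise a study report to JSON
#'
#' Flattens the numeric content of a [run_study()] report into a stable
#' JSON structure (deterministic for identical inputs).
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_json <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  roc_min <- function(r) if (is.null(r)) NULL else
    list(auc = r$auc, auc_ci = r$auc_ci)
  out <- list(
    n_subjects = report$n_subjects,
    admit_rate = report$admit_rate,
    correlation = report$correlation[c("r", "p", "n")],
    bland_altman = report$bland_altman[c("bias", "sd_diff", "loa_lower",
                                         "loa_upper", "prop_slope",
                                         "prop_slope_p", "n_pairs")],
    icc = list(
      crt = report$icc_crt[c("single", "average", "ci_single", "ci_average")],
      brt = report$icc_brt[c("single", "average", "ci_single", "ci_average")]),
    roc = list(brt_vs_abnormal_crt = roc_min(report$roc_brt_vs_crt),
               admission_brt = roc_min(report$roc_admission_brt),
               admission_crt = roc_min(report$roc_admission_crt)),
    optimal_cutoff_brt = report$optimal_cutoff_brt,
    diagnostics_brt = if (is.null(report$diagnostics_brt)) NULL else
      report$diagnostics_brt[c("tp", "fp", "fn", "tn", "sensitivity",
                               "specificity", "ppv", "npv")],
    summary = lapply(report$summary, function(m)
      if (is.null(m)) NULL else as.data.frame(m)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Process a batch of waveform files
#'
#' Measures BRT for every waveform CSV in `paths`. Failures are isolated:
#' an unreadable file or a fatal measurement error produces a row with an
#' error message and the batch continues.
#'
#' @param paths Character vector of waveform CSV paths.
#' @param protocol A [compression_protocol()] used when a file's sidecar
#'   carries no markers.
#' @param config A [brt_config()].
#' @return Data frame with one row per trial: `path`, `trial_id`, `brt`,
#'   `tau`, `r_squared`, `flags`, `error`.
#' @export
process_waveform_batch <- function(paths, protocol = compression_protocol(),
                                   config = brt_config()) {
  if (length(paths) == 0L) {
    warning("empty batch")
    return(data.frame(path = character(), trial_id = character(),
                      brt = numeric(), tau = numeric(),
                      r_squared = numeric(), flags = character(),
                      error = character()))
  }
  rows <- lapply(paths, function(p) {
    res <- tryCatch({
      tr <- read_waveform_csv(p)
      m <- measure_brt(tr, attr(tr, "protocol") %||% protocol, config)
      data.frame(path = p, trial_id = m$trial_id %||% NA_character_,
                 brt = m$brt, tau = m$fit$tau,
                 r_squared = m$fit$r_squared,
                 flags = paste(m$quality_flags, collapse = ";"),
                 error = NA_character_)
    }, error = function(e)
      data.frame(path = p, trial_id = NA_character_, brt = NA_real_,
                 tau = NA_real_, r_squared = NA_real_, flags = "",
                 error = conditionMessage(e)))
    res
  })
  do.call(rbind, rows)
}
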
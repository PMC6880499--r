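#' Measurement configuration for BRT
#'
#' Collects the tunable knobs of the measurement pipeline. Defaults follow
#' the device protocol (5-s compression, 16-ms sampling) and conservative
#' signal-processing choices documented in the methods vignette.
#'
#' @param smooth Suppress cardiac pulsation with a centered moving average
#'   before fitting (default `TRUE`).
#' @param smooth_window Moving-average window, seconds (default 0.5, near
#'   one cardiac cycle).
#' @param baseline_window Pre-compression window for the baseline median,
#'   seconds (default 2).
#' @param max_duration Maximum recovery length fitted, seconds (default 15).
#' @param tau_bounds Time-constant search bounds, seconds.
#' @param r_squared_warn R-squared below which a fit is flagged dubious.
#' @return A list of class `brt_config`.
#' @export
brt_config <- function(smooth = TRUE, smooth_window = 0.5,
                       baseline_window = 2.0, max_duration = 15.0,
                       tau_bounds = c(0.05, 60), r_squared_warn = 0.5) {
  structure(list(smooth = smooth, smooth_window = smooth_window,
                 baseline_window = baseline_window,
                 max_duration = max_duration, tau_bounds = tau_bounds,
                 r_squared_warn = r_squared_warn),
            class = "brt_config")
}

#' Measure blood refill time from a compression-release trace
#'
#' The central fitting routine: locates the compression window (beep
#' markers pass through; otherwise auto-detected), estimates the
#' pre-compression baseline, extracts the post-release recovery, optionally
#' smooths cardiac pulsation, fits the exponential recovery
#' \eqn{I(t) = B + A e^{-t/\tau}} by separable least squares, and reports
#' the time to 90% intensity return, \eqn{BRT = \tau \ln 10}.
#'
#' When smoothing is enabled, half a smoothing window is trimmed from each
#' end of the recovery before fitting: the centered moving average of an
#' exponential keeps the same time constant in the window interior but
#' biases the edge-truncated samples.
#'
#' @param trace A [ppg_trace()].
#' @param protocol A [compression_protocol()]; marker times in the trace's
#'   `protocol` attribute are used when `protocol` carries none.
#' @param config A [brt_config()].
#' @return An object of class `brt_fit`: list with `brt` (seconds, `NA` if
#'   the fit failed), `fit` (the `exp_fit`), `segment`, `baseline`,
#'   `window` (start/release times), `quality_flags`, `trial_id`.
#' @examples
#' sim <- simulate_waveform(tau = 1.5, noise_sd = 0, pulse_amplitude = 0)
#' m <- measure_brt(sim$trace)
#' brt(m)              # ~ 1.5 * log(10)
#' @seealso [brt()], [average_repeats()], [fit_exponential()], [compute_brt()]
#' @export
measure_brt <- function(trace, protocol = NULL, config = brt_config()) {
  stopifnot(inherits(trace, "ppg_trace"))
  if (is.null(protocol))
    protocol <- attr(trace, "protocol") %||% compression_protocol()
  win <- tryCatch(detect_compression_window(trace, protocol),
                  error = function(e) stop("stage detect: ", conditionMessage(e), call. = FALSE))
  baseline <- tryCatch(
    estimate_baseline(trace, win[["t_start"]], config$baseline_window),
    error = function(e) stop("stage baseline: ", conditionMessage(e), call. = FALSE))
  segment <- tryCatch(
    extract_recovery(trace, win[["t_release"]], baseline, config$max_duration),
    error = function(e) stop("stage extract: ", conditionMessage(e), call. = FALSE))

  fit_seg <- segment
  if (isTRUE(config$smooth)) {
    fit_seg <- smooth_pulsation(segment, config$smooth_window)
    half_n <- attr(fit_seg, "smooth_half_n") %||% 0L
    n <- length(fit_seg$rel_times)
    if (half_n > 0L && n - 2L * half_n >= 20L) {
      keep <- (half_n + 1L):(n - half_n)
      fit_seg$rel_times <- fit_seg$rel_times[keep] - fit_seg$rel_times[keep[1]]
      fit_seg$intensities <- fit_seg$intensities[keep]
    }
  }
  fit <- fit_exponential(fit_seg, tau_bounds = config$tau_bounds,
                         r_squared_warn = config$r_squared_warn)
  brt_val <- if (isTRUE(fit$converged)) compute_brt(fit) else NA_real_

  structure(
    list(brt = brt_val, fit = fit, segment = segment, fit_segment = fit_seg,
         baseline = baseline, window = win,
         quality_flags = fit$flags, trial_id = trace$trial_id,
         config = config),
    class = "brt_fit")
}

# Fatal flags invalidate the BRT value; warnings merely mark dubious fits.
fatal_flags <- c("short_segment", "no_convergence")

is_fatal <- function(x) {
  if (inherits(x, "brt_fit"))
    return(is.na(x$brt) || any(x$quality_flags %in% fatal_flags))
  is.na(x)
}

#' Extract the BRT value in seconds
#' @param x A `brt_fit`.
#' @return BRT in seconds (`NA` for a fatally flagged measurement).
#' @export
brt <- function(x) {
  stopifnot(inherits(x, "brt_fit"))
  x$brt
}

#' @export
print.brt_fit <- function(x, ...) {
  cat(sprintf("BRT measurement%s\n",
              if (!is.null(x$trial_id)) paste0(" [", x$trial_id, "]") else ""))
  if (is.na(x$brt)) {
    cat("  BRT: failed (", paste(x$quality_flags, collapse = ", "), ")\n", sep = "")
  } else {
    cat(sprintf("  BRT = %.3f s  (tau = %.3f s, 90%% return at tau*ln10)\n",
                x$brt, x$fit$tau))
  }
  cat(sprintf("  window: compression %.3f -> release %.3f s, baseline %.1f\n",
              x$window[["t_start"]], x$window[["t_release"]], x$baseline))
  cat(sprintf("  fit: A = %.2f, B = %.2f, R^2 = %.4f, n = %d\n",
              x$fit$A, x$fit$B, x$fit$r_squared, x$fit$n_points))
  if (length(x$quality_flags))
    cat("  flags:", paste(x$quality_flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.brt_fit <- function(object, ...) {
  out <- list(brt = object$brt, tau = object$fit$tau, A = object$fit$A,
              B = object$fit$B, r_squared = object$fit$r_squared,
              baseline = object$baseline,
              release_level = object$segment$release_level,
              n_points = object$fit$n_points,
              quality_flags = object$quality_flags,
              fatal = is_fatal(object))
  class(out) <- "summary.brt_fit"
  out
}

#' @export
print.summary.brt_fit <- function(x, ...) {
  cat("BRT measurement summary\n")
  cat(sprintf("  BRT %.3f s | tau %.3f s | amplitude %.2f | asymptote %.2f\n",
              x$brt, x$tau, x$A, x$B))
  cat(sprintf("  baseline %.2f, release level %.2f, R^2 %.4f (n = %d)\n",
              x$baseline, x$release_level, x$r_squared, x$n_points))
  cat("  quality:", if (length(x$quality_flags)) paste(x$quality_flags, collapse = ", ") else "ok",
      if (x$fatal) "[FATAL]\n" else "\n")
  invisible(x)
}

#' @export
coef.brt_fit <- function(object, ...) coef(object$fit)

#' @export
predict.brt_fit <- function(object, times = NULL, ...) {
  f <- object$fit
  if (is.null(times)) times <- object$fit_segment$rel_times
  f$B + f$A * exp(-times / f$tau)
}

#' @export
residuals.brt_fit <- function(object, ...) {
  object$fit_segment$intensities - predict(object)
}

#' @export
fitted.brt_fit <- function(object, ...) predict(object)

#' @export
plot.brt_fit <- function(x, ...) {
  seg <- x$segment
  graphics::plot(seg$rel_times, seg$intensities, type = "l", col = "grey50",
                 xlab = "time since release (s)",
                 ylab = "intensity (device units)",
                 main = sprintf("BRT = %.2f s", x$brt), ...)
  graphics::lines(x$fit_segment$rel_times +
                    (x$fit_segment$rel_times[1] - seg$rel_times[1]),
                  predict(x), col = "red", lwd = 2)
  graphics::abline(h = x$baseline, lty = 3)
  if (!is.na(x$brt)) graphics::abline(v = x$brt, lty = 2, col = "red")
  invisible(x)
}

#' Simulate traces from a fitted measurement
#'
#' Draws synthetic compression-release traces whose recovery has the fitted
#' amplitude, asymptote and time constant — a parametric-bootstrap view of
#' the measurement.
#'
#' @param object A converged `brt_fit`.
#' @param nsim Number of traces.
#' @param seed RNG seed.
#' @param ... Passed on to [simulate_waveform()] (e.g. `noise_sd`).
#' @return A list of `nsim` [ppg_trace()] objects.
#' @export
simulate.brt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!isTRUE(object$fit$converged)) stop("cannot simulate from an unconverged fit")
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seq_len(nsim), function(i) {
    simulate_waveform(tau = object$fit$tau, baseline = object$fit$B,
                      amplitude = object$fit$A, seed = seeds[i], ...)$trace
  })
}

#' Average triplicate refill-time measurements
#'
#' Per protocol each subject is measured three times and the per-subject
#' value is the arithmetic mean of the repeats. Fatally flagged
#' measurements (`NA`, short segment, no convergence) are dropped; a
#' warning notes when fewer than `expected_n` values survive.
#'
#' @param results Numeric vector of refill times (NA = failed), or a list
#'   of `brt_fit` objects and/or numbers.
#' @param expected_n Number of repeats the protocol calls for (default 3).
#' @return Mean refill time in seconds.
#' @examples
#' average_repeats(c(2.0, 2.5, 3.0))  # 2.5
#' @export
average_repeats <- function(results, expected_n = 3L) {
  if (is.list(results)) {
    vals <- vapply(results, function(r) {
      if (inherits(r, "brt_fit")) { if (is_fatal(r)) NA_real_ else r$brt }
      else as.numeric(r)
    }, numeric(1))
  } else vals <- as.numeric(results)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) stop("no usable measurements to average")
  if (length(vals) < expected_n)
    warning(sprintf("only %d of %d expected measurements usable", length(vals), expected_n))
  mean(vals)
}
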
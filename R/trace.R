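#' Construct a fingertip light-intensity trace
#'
#' A `ppg_trace` holds one uniformly sampled transmitted-light intensity
#' recording from a fingertip, as produced by a single-wavelength (infrared,
#' 940 nm) pulse-oximetry sensor around a timed compression-release trial.
#'
#' @param times Numeric vector of sample times in seconds from recording
#'   start. Must be strictly increasing on a uniform grid.
#' @param intensities Numeric vector of transmitted-light intensity in
#'   arbitrary device units; finite and non-negative.
#' @param sampling_interval Sampling interval in seconds (default 0.016,
#'   i.e. one sample every 16 ms).
#' @param wavelength_nm Light wavelength metadata (default 940).
#' @param trial_id Opaque trial label.
#'
#' @return An object of class `ppg_trace`: a list with elements `times`,
#'   `intensities`, `sampling_interval`, `wavelength_nm`, `trial_id`.
#' @examples
#' tr <- ppg_trace(seq(0, 1, by = 0.016), rep(500, 63))
#' print(tr)
#' @export
ppg_trace <- function(times, intensities, sampling_interval = 0.016,
                      wavelength_nm = 940, trial_id = NULL) {
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) != length(intensities))
    stop("`times` and `intensities` must have equal length")
  if (length(times) < 2L)
    stop("a trace needs at least 2 samples")
  d <- diff(times)
  if (any(d <= 0))
    stop("`times` must be strictly increasing")
  if (any(abs(d - sampling_interval) > 1e-9))
    stop("`times` must lie on a uniform grid with spacing `sampling_interval` (tolerance 1e-9 s)")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("`intensities` must be finite and non-negative")
  structure(
    list(times = times, intensities = intensities,
         sampling_interval = sampling_interval,
         wavelength_nm = wavelength_nm, trial_id = trial_id),
    class = "ppg_trace")
}

#' @export
print.ppg_trace <- function(x, ...) {
  cat(sprintf("PPG light-intensity trace%s\n",
              if (!is.null(x$trial_id)) paste0(" [", x$trial_id, "]") else ""))
  cat(sprintf("  %d samples @ %.0f ms, %.2f s span, wavelength %g nm\n",
              length(x$times), 1000 * x$sampling_interval,
              x$times[length(x$times)] - x$times[1], x$wavelength_nm))
  cat(sprintf("  intensity range [%.1f, %.1f] device units\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
plot.ppg_trace <- function(x, ...) {
  graphics::plot(x$times, x$intensities, type = "l",
                 xlab = "time (s)", ylab = "intensity (device units)",
                 main = x$trial_id %||% "PPG trace", ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a waveform CSV (plus optional metadata sidecar)
#'
#' The waveform format is a two-column CSV with header `time_s,intensity`,
#' one row per sample. An optional JSON sidecar (same path with extension
#' `.json`, or given explicitly) may carry `sampling_interval_s`,
#' `wavelength_nm`, `trial_id`, `t_start_s`, `t_release_s`; marker times are
#' returned as the `protocol` attribute.
#'
#' @param path CSV file path.
#' @param sidecar Optional path to the metadata JSON; by default the CSV
#'   path with its extension replaced by `.json` is used when it exists.
#' @return A `ppg_trace`; if the sidecar carried compression markers they
#'   are attached as `attr(trace, "protocol")` (a [compression_protocol()]).
#' @export
read_waveform_csv <- function(path, sidecar = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "intensity") %in% names(df)))
    stop("waveform CSV must have columns `time_s` and `intensity`: ", path)
  if (is.null(sidecar)) {
    cand <- sub("\\.[^.]+$", ".json", path)
    if (file.exists(cand) && cand != path) sidecar <- cand
  }
  meta <- list()
  if (!is.null(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dt <- meta$sampling_interval_s %||% stats::median(diff(df$time_s))
  tr <- ppg_trace(df$time_s, df$intensity, sampling_interval = dt,
                  wavelength_nm = meta$wavelength_nm %||% 940,
                  trial_id = meta$trial_id)
  if (!is.null(meta$t_start_s) || !is.null(meta$t_release_s)) {
    attr(tr, "protocol") <- compression_protocol(
      t_start = meta$t_start_s, t_release = meta$t_release_s)
  }
  tr
}

#' Write a waveform CSV and metadata sidecar
#'
#' @param trace A [ppg_trace()].
#' @param path Output CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param protocol Optional [compression_protocol()] whose markers are
#'   stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(trace, path, protocol = NULL) {
  stopifnot(inherits(trace, "ppg_trace"))
  utils::write.csv(
    data.frame(time_s = trace$times, intensity = trace$intensities),
    path, row.names = FALSE)
  meta <- list(sampling_interval_s = trace$sampling_interval,
               wavelength_nm = trace$wavelength_nm,
               trial_id = trace$trial_id)
  if (is.null(protocol)) protocol <- attr(trace, "protocol")
  if (!is.null(protocol)) {
    meta$t_start_s <- protocol$t_start
    meta$t_release_s <- protocol$t_release
  }
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       sub("\\.[^.]+$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Describe the timed compression protocol
#'
#' The measurement protocol compresses the fingertip for a fixed duration
#' (5 s, signalled by start/release beeps) and then releases. Marker times,
#' when recorded, make segmentation exact; without them the compression
#' window is auto-detected from the trace.
#'
#' @param compression_duration Compression length in seconds (default 5).
#' @param t_start,t_release Optional absolute marker times (seconds).
#' @return An object of class `compression_protocol`.
#' @export
compression_protocol <- function(compression_duration = 5.0,
                                 t_start = NULL, t_release = NULL) {
  if (!is.null(compression_duration) && compression_duration <= 0)
    stop("`compression_duration` must be positive")
  if (!is.null(t_start) && !is.null(t_release)) {
    if (abs((t_release - t_start) - compression_duration) > 0.1)
      stop("markers disagree with `compression_duration` by more than 0.1 s")
  }
  structure(list(compression_duration = compression_duration,
                 t_start = t_start, t_release = t_release),
            class = "compression_protocol")
}
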
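# Segmentation of a compression-release trial: window detection, baseline,
# recovery extraction, pulsation smoothing.

# Centered moving average with edge truncation: at each sample the mean is
# taken over the part of the window that lies inside the signal.
moving_average <- function(x, half_n) {
  if (half_n < 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_n, 1L)
  hi <- pmin(seq_len(n) + half_n, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Window width in samples for a time window `w` (seconds): odd, >= 1.
window_half_n <- function(w, dt) max(0L, floor(w / dt / 2))

#' Locate the compression window of a trial
#'
#' When the protocol carries beep-marker times they pass through unchanged.
#' Otherwise the window is auto-detected: the start is the onset of the
#' largest sustained intensity rise (the 0.5-s-smoothed trace exceeding the
#' provisional baseline by 5 pre-compression ripple SDs for at least 1 s,
#' refined to the first raw sample above threshold) and the release is the
#' subsequent maximum of the negative first difference.
#'
#' @param trace A [ppg_trace()].
#' @param protocol A [compression_protocol()].
#' @return Named numeric vector `c(t_start=, t_release=)` in seconds.
#' @export
detect_compression_window <- function(trace, protocol = compression_protocol()) {
  stopifnot(inherits(trace, "ppg_trace"))
  tt <- trace$times; ii <- trace$intensities; dt <- trace$sampling_interval
  if (!is.null(protocol$t_start) && !is.null(protocol$t_release)) {
    if (protocol$t_start < tt[1] || protocol$t_release > tt[length(tt)])
      stop("compression markers lie outside the trace span")
    return(c(t_start = protocol$t_start, t_release = protocol$t_release))
  }
  # provisional baseline and ripple from the first 2 s
  pre <- ii[tt < tt[1] + 2.0]
  if (length(pre) < 10L) stop("no-compression: trace too short for detection")
  base <- stats::median(pre)
  ripple <- stats::sd(pre)
  thr <- base + max(5 * ripple, 1e-9)
  sm <- moving_average(ii, window_half_n(0.5, dt))
  above <- sm > thr
  # first run of `above` lasting >= 1 s
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  need <- ceiling(1.0 / dt)
  hit <- which(r$values & r$lengths >= need)
  if (length(hit) == 0L) stop("no-compression: no sustained intensity rise detected")
  k0 <- starts[hit[1]]
  # refine: first raw sample above threshold within half a smoothing window
  # of the smoothed crossing (centered smoothing anticipates the rise)
  lo <- max(1L, k0 - window_half_n(0.5, dt))
  raw_hit <- which(ii[lo:length(ii)] > thr)[1]
  if (!is.na(raw_hit)) k0 <- lo + raw_hit - 1L
  t_start <- tt[k0]
  # release: steepest raw fall after the start
  after <- k0:(length(ii) - 1L)
  d1 <- ii[after + 1L] - ii[after]
  krel <- after[which.min(d1)]
  t_release <- tt[krel]
  dur <- t_release - t_start
  if (!is.null(protocol$compression_duration) &&
      abs(dur - protocol$compression_duration) > 0.2 * protocol$compression_duration)
    warning(sprintf("detected compression length %.2f s deviates from protocol %.1f s by > 20%%",
                    dur, protocol$compression_duration))
  c(t_start = t_start, t_release = t_release)
}

#' Estimate the pre-compression baseline intensity
#'
#' Median intensity over the `window` seconds immediately before the
#' compression start; the median resists cardiac pulsatile ripple.
#'
#' @param trace A [ppg_trace()].
#' @param t_start Compression start time (seconds).
#' @param window Baseline window length in seconds (default 2).
#' @return Baseline intensity (device units).
#' @export
estimate_baseline <- function(trace, t_start, window = 2.0) {
  stopifnot(inherits(trace, "ppg_trace"))
  sel <- trace$times >= t_start - window & trace$times < t_start
  # require (nearly) the full window of pre-compression samples
  if (sum(sel) < floor(window / trace$sampling_interval) - 1L)
    stop("short-baseline: fewer than ", window,
         " s of samples before the compression start")
  stats::median(trace$intensities[sel])
}

#' Extract the post-release recovery segment
#'
#' Cuts the trace from the release marker forward, re-zeroes time at the
#' first post-release sample, and carries the baseline and release-level
#' intensities through for polarity checks.
#'
#' @param trace A [ppg_trace()].
#' @param t_release Release time (seconds, absolute).
#' @param baseline Pre-compression baseline intensity.
#' @param max_duration Maximum recovery length to keep, seconds (default 15).
#' @return An object of class `recovery_segment`: list with `t_release`,
#'   `rel_times` (seconds since release, starting at 0), `intensities`,
#'   `baseline`, `release_level`, `sampling_interval`, `polarity_ok`.
#' @export
extract_recovery <- function(trace, t_release, baseline, max_duration = 15.0) {
  stopifnot(inherits(trace, "ppg_trace"))
  tt <- trace$times
  if (t_release < tt[1] || t_release > tt[length(tt)])
    stop("`t_release` lies outside the trace")
  sel <- tt >= t_release & tt <= t_release + max_duration
  if (sum(sel) < 20L)
    stop("short-segment: fewer than 20 post-release samples")
  rel <- tt[sel]
  ii <- trace$intensities[sel]
  structure(
    list(t_release = t_release,
         rel_times = rel - rel[1],
         intensities = ii,
         baseline = baseline,
         release_level = ii[1],
         sampling_interval = trace$sampling_interval,
         polarity_ok = ii[1] >= baseline),
    class = "recovery_segment")
}

#' Suppress cardiac pulsation by a centered moving average
#'
#' A centered moving average with a window near one cardiac cycle
#' (default 0.5 s) attenuates the pulsatile ripple superimposed on the
#' recovery while leaving an exponential's time constant unchanged in the
#' window interior. Edges are truncated (partial-window means).
#'
#' @param segment A `recovery_segment`.
#' @param window Smoothing window in seconds (default 0.5). A window
#'   shorter than one sampling interval is a no-op with a warning.
#' @return The segment with smoothed intensities; `rel_times` unchanged.
#' @export
smooth_pulsation <- function(segment, window = 0.5) {
  stopifnot(inherits(segment, "recovery_segment"))
  dt <- segment$sampling_interval
  if (window < dt) {
    warning("smoothing window shorter than one sample; returning segment unchanged")
    return(segment)
  }
  half_n <- window_half_n(window, dt)
  segment$intensities <- moving_average(segment$intensities, half_n)
  segment$release_level <- segment$intensities[1]
  attr(segment, "smooth_half_n") <- half_n
  segment
}
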
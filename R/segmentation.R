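#' Detect the synchronization tap in a recording
#'
#' The tap produces an abrupt amplitude increase on the accelerometer channel.
#' Detection is deviation-from-baseline: using the first `baseline_s` seconds
#' as baseline, the event time is the first post-baseline sample whose
#' absolute deviation from the baseline mean exceeds
#' `threshold_sd x baseline SD`. This time becomes t = 0 for cross-system
#' alignment.
#'
#' @param recording A [ts_recording()].
#' @param channel Channel label or index carrying the tap.
#' @param threshold_sd Detection threshold as a multiple of the baseline SD.
#' @param baseline_s Length of the baseline window, seconds.
#' @return Event time in seconds (on the recording's own time axis).
#' @export
detect_sync_event <- function(recording, channel = 1L, threshold_sd = 8,
                              baseline_s = 0.5) {
  stopifnot(inherits(recording, "ts_recording"))
  x <- rec_channel(recording, channel)
  t <- rec_times(recording)
  nb <- sum(t < t[1L] + baseline_s)
  if (nb < 2L || nb >= length(x))
    stop("recording too short for the baseline window", call. = FALSE)
  m <- mean(x[seq_len(nb)])
  s <- stats::sd(x[seq_len(nb)])
  post <- (nb + 1L):length(x)
  hit <- which(abs(x[post] - m) > threshold_sd * s)
  if (!length(hit))
    stop("no synchronization event detected (no sample exceeds ",
         threshold_sd, " baseline SDs)", call. = FALSE)
  t[post[hit[1L]]]
}

#' Trim a recording to the task window
#'
#' Keeps samples in the half-open window `[start_s, end_s)` and rebases the
#' time axis to 0, so trimmed recordings from different systems share a common
#' task clock.
#'
#' @param recording A [ts_recording()].
#' @param start_s,end_s Window bounds in seconds, `start_s < end_s`, both
#'   within the recording span.
#' @return The trimmed [ts_recording()] (start time 0).
#' @export
trim_to_task <- function(recording, start_s, end_s) {
  stopifnot(inherits(recording, "ts_recording"))
  if (start_s >= end_s) stop("start_s must be < end_s", call. = FALSE)
  t <- rec_times(recording)
  t_end <- recording$start_s + n_samples(recording) / recording$rate_hz
  if (start_s < recording$start_s - 1e-9 || end_s > t_end + 1e-9)
    stop("trim window lies outside the recording span", call. = FALSE)
  keep <- which(t >= start_s & t < end_s)
  ts_recording(recording$data[keep, , drop = FALSE], recording$rate_hz,
               start_s = 0, units = recording$units)
}

#' Split a recording into per-cycle sub-recordings
#'
#' One sub-recording per annotated cycle, half-open `[start, end)` windows on
#' the recording's time axis so no sample is assigned to two cycles.
#'
#' @param recording A [ts_recording()].
#' @param annotation A [cycle_annotation()]; every cycle must lie within the
#'   recording span.
#' @return A list of [ts_recording()], one per cycle (empty list for an empty
#'   annotation). Each keeps its original start time.
#' @export
split_cycles <- function(recording, annotation) {
  stopifnot(inherits(recording, "ts_recording"),
            inherits(annotation, "cycle_annotation"))
  t <- rec_times(recording)
  t_end <- recording$start_s + n_samples(recording) / recording$rate_hz
  out <- vector("list", nrow(annotation))
  for (k in seq_len(nrow(annotation))) {
    s <- annotation$start_s[k]; e <- annotation$end_s[k]
    if (s < recording$start_s - 1e-9 || e > t_end + 1e-9)
      stop(sprintf("cycle %d [%.3f, %.3f) lies outside the recording span",
                   k, s, e), call. = FALSE)
    keep <- which(t >= s & t < e)
    out[[k]] <- ts_recording(recording$data[keep, , drop = FALSE],
                             recording$rate_hz, start_s = s,
                             units = recording$units)
  }
  out
}
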
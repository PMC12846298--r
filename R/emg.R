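#' EMG amplitude chain
#'
#' The chain applied identically to the wearable and the reference recording:
#' ADC counts to volts, mean-offset correction, full-wave rectification, 1 s
#' moving-average envelope, per-cycle split, fixed-length (1700-point)
#' resampling by mirror padding, per-cycle 0-1 normalization, mean of the
#' normalized repetitions, and the RMS of that mean waveform. Because of the
#' per-cycle normalization the final RMS is invariant to any positive affine
#' transform of the raw signal, which makes the ADC constants immaterial to
#' the agreement results.
#'
#' @name emg_chain
NULL

#' Convert ADC counts to volts
#'
#' Mid-scale referenced transfer function
#' `v = (raw / (2^bits - 1) - 0.5) * vref / gain`. Values outside the
#' converter range raise a clipping warning (and are kept).
#'
#' @param raw Numeric vector of ADC readings (counts).
#' @param adc_bits Converter resolution in bits (>= 1).
#' @param vref_volts Reference voltage (> 0).
#' @param gain Analog amplifier gain (> 0).
#' @return Signal in volts.
#' @export
counts_to_volts <- function(raw, adc_bits = 12, vref_volts = 3.3,
                            gain = 1000) {
  if (adc_bits < 1 || vref_volts <= 0 || gain <= 0)
    stop("invalid ADC transfer parameters", call. = FALSE)
  full_scale <- 2^adc_bits - 1
  if (any(raw < 0 | raw > full_scale))
    warning("raw values outside [0, 2^bits - 1]: converter would clip",
            call. = FALSE)
  (raw / full_scale - 0.5) * vref_volts / gain
}

#' Remove the mean offset
#' @param x Numeric vector.
#' @return `x - mean(x)` (zero-mean output).
#' @export
remove_offset <- function(x) {
  if (!length(x)) stop("empty signal", call. = FALSE)
  x - mean(x)
}

#' Full-wave rectification
#' @param x Numeric vector.
#' @return Elementwise absolute value.
#' @export
full_wave_rectify <- function(x) abs(x)

#' Moving-average envelope
#'
#' Centered moving mean over `round(window_s * rate_hz)` samples. Edges are
#' handled by reflecting the signal, which avoids the edge droop that would
#' otherwise bias the per-cycle min/max used downstream by the 0-1
#' normalization.
#'
#' @param x Rectified (non-negative) signal.
#' @param window_s Averaging window in seconds.
#' @param rate_hz Sampling rate in samples/s.
#' @return Envelope of the same length as `x`.
#' @export
moving_average_envelope <- function(x, window_s = 1.0, rate_hz) {
  w <- round(window_s * rate_hz)
  if (w < 1) stop("window must span at least one sample", call. = FALSE)
  n <- length(x)
  if (w > n) stop("averaging window longer than the signal", call. = FALSE)
  if (w == 1L) return(x)
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  pre <- if (left > 0L) x[left:1L] else numeric(0)
  post <- if (right > 0L) x[n:(n - right + 1L)] else numeric(0)
  xp <- c(pre, x, post)
  cs <- cumsum(c(0, xp))
  (cs[(w + 1L):(n + w)] - cs[1L:n]) / w
}

#' Resample a cycle to a fixed length by mirror padding
#'
#' Builds the mirrored extension `[rev(x), x, rev(x)]`, linearly resamples it
#' to `3 * target_len` points, and returns the central `target_len` block.
#' When the cycle already has `target_len` samples this is exactly the
#' identity.
#'
#' @param x Numeric vector, length >= 2.
#' @param target_len Output length (1700 by default).
#' @return Numeric vector of length `target_len`.
#' @export
resample_mirror_central <- function(x, target_len = 1700) {
  n <- length(x)
  if (n < 2L) stop("cycle must contain at least 2 samples", call. = FALSE)
  xm <- c(rev(x), x, rev(x))
  pos <- seq(0, 3 * n - 1, length.out = 3 * target_len)
  y <- stats::approx(seq(0, 3 * n - 1), xm, xout = pos)$y
  y[(target_len + 1L):(2L * target_len)]
}

#' Normalize a cycle to the 0-1 range
#'
#' `(x - min) / (max - min)`. A constant (degenerate) cycle maps to all zeros
#' and is flagged via the `"degenerate"` attribute.
#'
#' @param cycle Numeric vector.
#' @return Normalized vector with a logical `"degenerate"` attribute.
#' @export
normalize_01 <- function(cycle) {
  if (!length(cycle)) stop("empty cycle", call. = FALSE)
  rng <- range(cycle)
  if (rng[2] == rng[1]) {
    out <- rep(0, length(cycle))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (cycle - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate") <- FALSE
  out
}

#' Mean waveform across repetitions
#'
#' Pointwise arithmetic mean of the normalized cycles (rows).
#'
#' @param matrix Numeric matrix, cycles x points; all rows the same length.
#' @return Numeric vector of column means.
#' @export
mean_cycle <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (!nrow(matrix)) stop("no cycles to average", call. = FALSE)
  colMeans(matrix)
}

#' Root mean square of a waveform
#' @param waveform Non-empty numeric vector.
#' @return `sqrt(mean(waveform^2))`.
#' @export
rms <- function(waveform) {
  if (!length(waveform)) stop("empty waveform", call. = FALSE)
  sqrt(mean(waveform^2))
}

#' Run the full EMG amplitude chain on one recording
#'
#' Applies the chain documented in [emg_chain] to every muscle channel of a
#' recording: the recording is trimmed to the task window (first cycle start
#' to last cycle end), the envelope is computed on the trimmed signal, and
#' cycles are then split, resampled, normalized and averaged. Per-repetition
#' RMS values (RMS of each normalized resampled cycle) are recorded for
#' intra-device reliability and CV computations.
#'
#' @param recording A [ts_recording()] with one column per muscle, ADC counts.
#' @param annotation A [cycle_annotation()].
#' @param adc_bits,vref_volts,gain ADC transfer constants
#'   (see [counts_to_volts()]).
#' @param envelope_window_s Moving-average window, seconds.
#' @param target_len Fixed cycle length after resampling.
#' @return A data frame with one row per muscle x repetition plus the
#'   repetition-0 row holding the headline RMS of the mean waveform: columns
#'   `muscle`, `repetition` (0 = mean waveform), `rms`, `degenerate`.
#' @export
run_emg_pipeline <- function(recording, annotation, adc_bits = 12,
                             vref_volts = 3.3, gain = 1000,
                             envelope_window_s = 1.0, target_len = 1700) {
  stopifnot(inherits(recording, "ts_recording"),
            inherits(annotation, "cycle_annotation"))
  task0 <- min(annotation$start_s); task1 <- max(annotation$end_s)
  trimmed <- trim_to_task(recording, task0, task1)
  ann0 <- cycle_annotation(annotation$start_s - task0,
                           annotation$end_s - task0)
  muscles <- colnames(trimmed$data)
  nc <- nrow(ann0)
  out <- vector("list", length(muscles))
  for (m in seq_along(muscles)) {
    v <- counts_to_volts(rec_channel(trimmed, muscles[m]), adc_bits,
                         vref_volts, gain)
    env <- moving_average_envelope(full_wave_rectify(remove_offset(v)),
                                   envelope_window_s, trimmed$rate_hz)
    env_rec <- ts_recording(env, trimmed$rate_hz, channels = muscles[m])
    cycles <- split_cycles(env_rec, ann0)
    norm <- matrix(NA_real_, nc, target_len)
    degen <- logical(nc)
    for (k in seq_len(nc)) {
      res <- resample_mirror_central(rec_channel(cycles[[k]], 1L), target_len)
      nk <- normalize_01(res)
      degen[k] <- isTRUE(attr(nk, "degenerate"))
      norm[k, ] <- nk
    }
    rep_rms <- apply(norm, 1L, rms)
    mean_rms <- rms(mean_cycle(norm))
    out[[m]] <- data.frame(
      muscle = muscles[m], repetition = c(0L, seq_len(nc)),
      rms = c(mean_rms, rep_rms), degenerate = c(any(degen), degen))
  }
  do.call(rbind, out)
}
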
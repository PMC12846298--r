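#' Multichannel time-series recording
#'
#' Container for a uniformly sampled multichannel recording (EMG channels in
#' ADC counts, Euler-angle streams in degrees, accelerometer traces, ...).
#' Samples are stored as an `n x C` numeric matrix; sample times are implied
#' by `start_s` and `rate_hz` (time of sample `i` is `start_s + (i-1)/rate_hz`).
#'
#' @param data Numeric matrix (`n` samples x `C` channels) or a numeric vector
#'   for a single channel.
#' @param rate_hz Sampling rate in samples per second (> 0).
#' @param channels Character vector of channel labels; defaults to the column
#'   names of `data` or `ch1`, `ch2`, ...
#' @param start_s Time of the first sample, seconds.
#' @param units Free-text unit label carried along for reporting.
#'
#' @return An object of class `ts_recording`.
#' @export
ts_recording <- function(data, rate_hz, channels = NULL, start_s = 0,
                         units = "au") {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("`rate_hz` must be a single positive number", call. = FALSE)
  if (is.null(channels)) {
    channels <- colnames(data)
    if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(data)))
  }
  if (length(channels) != ncol(data))
    stop("channel labels do not match the number of data columns",
         call. = FALSE)
  colnames(data) <- channels
  structure(
    list(data = data, rate_hz = rate_hz, start_s = start_s, units = units),
    class = "ts_recording"
  )
}

#' @export
print.ts_recording <- function(x, ...) {
  cat(sprintf(
    "<ts_recording> %d samples x %d channels @ %g Hz, t = [%.3f, %.3f) s\n",
    nrow(x$data), ncol(x$data), x$rate_hz, x$start_s,
    x$start_s + nrow(x$data) / x$rate_hz))
  cat("channels:", paste(colnames(x$data), collapse = ", "), "\n")
  invisible(x)
}

#' Sample times of a recording
#'
#' @param x A [ts_recording()].
#' @return Numeric vector of sample times in seconds.
#' @export
rec_times <- function(x) {
  stopifnot(inherits(x, "ts_recording"))
  x$start_s + (seq_len(nrow(x$data)) - 1L) / x$rate_hz
}

#' Number of samples in a recording
#' @param x A [ts_recording()].
#' @return Integer sample count.
#' @export
n_samples <- function(x) nrow(x$data)

#' Duration of a recording in seconds
#' @param x A [ts_recording()].
#' @return Span in seconds (`n / rate`).
#' @export
rec_duration <- function(x) nrow(x$data) / x$rate_hz

#' Extract one channel as a numeric vector
#' @param x A [ts_recording()].
#' @param channel Channel label or index.
#' @return Numeric vector of samples.
#' @export
rec_channel <- function(x, channel) {
  stopifnot(inherits(x, "ts_recording"))
  if (is.character(channel) && !channel %in% colnames(x$data))
    stop("unknown channel: ", channel, call. = FALSE)
  as.numeric(x$data[, channel])
}

#' Write / read a recording as CSV
#'
#' The interchange format is one `time_s` column plus one column per channel,
#' with a header row of labels.
#'
#' @param x A [ts_recording()].
#' @param path File path.
#' @return `write_recording_csv()` returns `path` invisibly;
#'   `read_recording_csv()` returns a [ts_recording()] (the rate is recovered
#'   from the median time step).
#' @export
write_recording_csv <- function(x, path) {
  stopifnot(inherits(x, "ts_recording"))
  df <- data.frame(time_s = rec_times(x), x$data, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop("recording CSV must contain a `time_s` column", call. = FALSE)
  t <- df$time_s
  if (length(t) < 2L) stop("recording CSV has fewer than 2 samples",
                           call. = FALSE)
  rate <- 1 / stats::median(diff(t))
  ts_recording(as.matrix(df[setdiff(names(df), "time_s")]),
               rate_hz = rate, start_s = t[1L])
}
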
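#' Cycle annotations derived from video
#'
#' Task repetitions are segmented manually from video; each cycle is a
#' half-open `[start_s, end_s)` interval on the shared time axis. Time in
#' seconds — not sample index — is the interchange currency between the 30
#' frames/s video, the 100 Hz IMU stream and the 1000 Hz EMG stream.
#'
#' @param start_s,end_s Numeric vectors of cycle start/end times, seconds.
#' @param fps Frame rate used for the frame-to-seconds conversion (recorded
#'   for provenance; `NA` if the annotation was not video-derived).
#' @param source Free-text provenance label.
#' @return A data frame of class `cycle_annotation` with columns
#'   `cycle`, `start_s`, `end_s`.
#' @export
cycle_annotation <- function(start_s, end_s, fps = NA_real_,
                             source = "manual") {
  if (length(start_s) != length(end_s))
    stop("`start_s` and `end_s` must have equal length", call. = FALSE)
  if (any(end_s <= start_s))
    stop("every cycle must satisfy start_s < end_s", call. = FALSE)
  if (length(start_s) > 1L) {
    o <- order(start_s)
    start_s <- start_s[o]; end_s <- end_s[o]
    if (any(start_s[-1L] < end_s[-length(end_s)]))
      stop("cycles must be non-overlapping", call. = FALSE)
  }
  if (!is.na(fps) && fps <= 0) stop("`fps` must be positive", call. = FALSE)
  structure(
    data.frame(cycle = seq_along(start_s), start_s = start_s, end_s = end_s),
    fps = fps, source = source,
    class = c("cycle_annotation", "data.frame")
  )
}

#' Convert a video frame index to seconds
#'
#' @param frame_index Frame number (0-based count, >= 0).
#' @param fps Frame rate of the video in frames per second (> 0).
#' @return Time in seconds (`frame_index / fps`).
#' @export
frames_to_seconds <- function(frame_index, fps) {
  if (any(frame_index < 0)) stop("frame index must be >= 0", call. = FALSE)
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  frame_index / fps
}

#' Mean and SD of cycle durations
#'
#' Sample SD (n - 1 denominator). With a single cycle the SD is reported as 0
#' and a warning is raised.
#'
#' @param annotation A [cycle_annotation()].
#' @return Named numeric vector `c(mean_s, sd_s)`.
#' @export
cycle_duration_stats <- function(annotation) {
  stopifnot(inherits(annotation, "cycle_annotation"))
  d <- annotation$end_s - annotation$start_s
  if (!length(d)) stop("annotation contains no cycles", call. = FALSE)
  if (length(d) == 1L) {
    warning("single cycle: SD of durations reported as 0", call. = FALSE)
    return(c(mean_s = d, sd_s = 0))
  }
  c(mean_s = mean(d), sd_s = stats::sd(d))
}

#' Write / read a cycle annotation as CSV
#'
#' `read_annotation_csv()` accepts either time columns (`start_s`, `end_s`) or
#' frame columns (`start_frame`, `end_frame`) converted with the file's `fps`
#' column or the `fps` argument.
#'
#' @param annotation A [cycle_annotation()].
#' @param path File path.
#' @param fps Frame rate used when the CSV carries frame indices.
#' @return `write_annotation_csv()` returns `path` invisibly;
#'   `read_annotation_csv()` returns a [cycle_annotation()].
#' @export
write_annotation_csv <- function(annotation, path) {
  stopifnot(inherits(annotation, "cycle_annotation"))
  utils::write.csv(as.data.frame(annotation), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_csv
#' @export
read_annotation_csv <- function(path, fps = NA_real_) {
  df <- utils::read.csv(path)
  if (all(c("start_s", "end_s") %in% names(df))) {
    cycle_annotation(df$start_s, df$end_s, fps = fps, source = path)
  } else if (all(c("start_frame", "end_frame") %in% names(df))) {
    if ("fps" %in% names(df)) fps <- df$fps[1L]
    if (is.na(fps))
      stop("frame-indexed annotation needs an `fps` column or argument",
           call. = FALSE)
    cycle_annotation(frames_to_seconds(df$start_frame, fps),
                     frames_to_seconds(df$end_frame, fps),
                     fps = fps, source = path)
  } else {
    stop("annotation CSV needs start_s/end_s or start_frame/end_frame columns",
         call. = FALSE)
  }
}
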
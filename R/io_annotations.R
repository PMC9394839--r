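#' Spindle event intervals
#'
#' An annotated spindle interval: onset and duration in seconds from recording
#' start (half-open interval `[onset, onset + duration)`), with the mean
#' expert score in `[0, 1]`.
#'
#' @param onset_s Onset times in seconds (>= 0).
#' @param duration_s Durations in seconds (> 0).
#' @param score Mean expert scores in `[0, 1]`.
#' @return A data frame of class `"spindle_events"` with columns
#'   `onset_s`, `duration_s`, `score`.
#' @export
spindle_events <- function(onset_s = numeric(), duration_s = numeric(),
                           score = numeric()) {
  onset_s <- as.numeric(onset_s); duration_s <- as.numeric(duration_s)
  score <- as.numeric(score)
  n <- length(onset_s)
  stopifnot(length(duration_s) == n, length(score) == n)
  if (any(onset_s < 0)) stop("onset_s must be >= 0", call. = FALSE)
  if (any(duration_s <= 0)) stop("duration_s must be > 0", call. = FALSE)
  if (any(score < 0 | score > 1)) stop("score must be in [0, 1]", call. = FALSE)
  structure(
    data.frame(onset_s = onset_s, duration_s = duration_s, score = score),
    class = c("spindle_events", "data.frame")
  )
}

#' Read or write spindle annotations
#'
#' Annotations travel as a plain CSV with header `onset_s,duration_s,score`,
#' times in seconds written at millisecond resolution.
#'
#' @param path CSV file path.
#' @return `read_annotations()` returns a [spindle_events()] data frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  df <- read.csv(path, colClasses = "numeric")
  need <- c("onset_s", "duration_s", "score")
  if (!all(need %in% names(df))) {
    stop("annotation CSV must have header onset_s,duration_s,score", call. = FALSE)
  }
  bad <- which(df$duration_s <= 0)
  if (length(bad)) {
    stop(sprintf("invalid annotation: non-positive duration at row %d", bad[1]),
         call. = FALSE)
  }
  spindle_events(df$onset_s, df$duration_s, df$score)
}

#' @param events A [spindle_events()] data frame.
#' @rdname read_annotations
#' @export
write_annotations <- function(events, path) {
  df <- data.frame(
    onset_s = sprintf("%.3f", events$onset_s),
    duration_s = sprintf("%.3f", events$duration_s),
    score = sprintf("%.6f", events$score)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a recording into streaming chunks
#'
#' Emulates sample-by-sample acquisition: the concatenation of the returned
#' blocks is exactly the input sample vector, for any chunk size down to 1.
#'
#' @param rec An [eeg_recording()] or a numeric vector.
#' @param chunk_samples Maximum samples per block (>= 1).
#' @return A list of numeric blocks.
#' @export
stream_chunks <- function(rec, chunk_samples) {
  x <- if (inherits(rec, "eeg_recording")) rec$samples else as.numeric(rec)
  stop_if_not_scalar_number(chunk_samples, "chunk_samples")
  if (chunk_samples < 1) stop("chunk_samples must be >= 1", call. = FALSE)
  if (!length(x)) return(list())
  starts <- seq(1L, length(x), by = as.integer(chunk_samples))
  lapply(starts, function(s) x[s:min(s + chunk_samples - 1L, length(x))])
}
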
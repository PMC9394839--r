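# Consensus-score binarization and post-processing.
#
# Expert-consensus spindle annotation assigns each sample a mean score in
# [0, 1]. Binary spindle labels are obtained by thresholding the score
# (0.2 for the younger cohort, 0.35 for the older cohort), then merging
# intervals closer than 0.1 s and discarding intervals shorter than 0.3 s or
# longer than 2.5 s.

#' Label post-processing configuration
#'
#' @param score_threshold Binarization cutoff on the mean expert score
#'   (0.2 for the younger cohort, 0.35 for the older one).
#' @param min_dur_s Minimum kept duration in seconds (default 0.3).
#' @param max_dur_s Maximum kept duration in seconds (default 2.5).
#' @param merge_gap_s Gaps shorter than this are merged (default 0.1).
#' @param strict_merge If `TRUE`, merge a gap only when at least one of its
#'   two neighbours is itself shorter than `min_dur_s` (the conservative
#'   reading of the merge rule). Default `FALSE`: merge on gap alone.
#' @return An object of class `"label_config"`.
#' @export
label_config <- function(score_threshold = 0.2, min_dur_s = 0.3,
                         max_dur_s = 2.5, merge_gap_s = 0.1,
                         strict_merge = FALSE) {
  stopifnot(score_threshold > 0, score_threshold < 1,
            min_dur_s > 0, min_dur_s < max_dur_s, merge_gap_s > 0)
  structure(list(score_threshold = score_threshold, min_dur_s = min_dur_s,
                 max_dur_s = max_dur_s, merge_gap_s = merge_gap_s,
                 strict_merge = strict_merge),
            class = "label_config")
}

#' Default score threshold for a cohort
#'
#' @param cohort `"younger"` (threshold 0.2) or `"older"` (threshold 0.35).
#' @return The binarization threshold.
#' @export
cohort_threshold <- function(cohort) {
  switch(cohort, younger = 0.2, older = 0.35,
         stop("cohort must be 'younger' or 'older'", call. = FALSE))
}

#' Binarize a per-sample score series into raw intervals
#'
#' Maximal runs of samples with `score >= threshold` become half-open
#' intervals `[onset, offset)` in seconds (sample `n`, 0-based, covers
#' `[n/fs, (n+1)/fs)`).
#'
#' @param score_series Numeric vector of per-sample scores in `[0, 1]`.
#' @param fs_hz Sampling rate of the series.
#' @param threshold Binarization cutoff.
#' @return A data frame with columns `onset_s`, `offset_s`.
#' @export
moda_binarize <- function(score_series, fs_hz, threshold) {
  if (any(score_series < 0 | score_series > 1)) {
    stop("scores must be in [0, 1]", call. = FALSE)
  }
  pos <- score_series >= threshold
  if (!any(pos)) return(data.frame(onset_s = numeric(), offset_s = numeric()))
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(onset_s = (starts[keep] - 1L) / fs_hz,
             offset_s = ends[keep] / fs_hz)
}

#' Merge close intervals and filter by duration
#'
#' Applies the two label post-processing rules in order: (1) repeatedly merge
#' consecutive intervals whose gap is smaller than `merge_gap_s` (the merged
#' interval spans from the first onset to the last offset) until no gap
#' qualifies; (2) drop intervals shorter than `min_dur_s` or longer than
#' `max_dur_s`. The operation is idempotent.
#'
#' @param intervals Data frame with `onset_s`, `offset_s`, sorted and
#'   non-overlapping.
#' @param config A [label_config()].
#' @return Filtered data frame with `onset_s`, `offset_s`, `duration_s`.
#' @export
moda_postprocess <- function(intervals, config = label_config()) {
  n <- nrow(intervals)
  if (n == 0L) {
    return(data.frame(onset_s = numeric(), offset_s = numeric(),
                      duration_s = numeric()))
  }
  on <- intervals$onset_s; off <- intervals$offset_s
  if (is.unsorted(on, strictly = FALSE) || any(off[-n] > on[-1] + 1e-12)) {
    stop("intervals must be sorted and non-overlapping", call. = FALSE)
  }
  # left-to-right merge to fixpoint: chains of close intervals collapse
  m_on <- on[1]; m_off <- off[1]
  res_on <- numeric(); res_off <- numeric()
  for (i in seq_len(n - 1L) + 1L) {
    gap <- on[i] - m_off
    short_pair <- (m_off - m_on < config$min_dur_s) ||
      (off[i] - on[i] < config$min_dur_s)
    do_merge <- gap < config$merge_gap_s &&
      (!config$strict_merge || short_pair)
    if (do_merge) {
      m_off <- off[i]
    } else {
      res_on <- c(res_on, m_on); res_off <- c(res_off, m_off)
      m_on <- on[i]; m_off <- off[i]
    }
  }
  res_on <- c(res_on, m_on); res_off <- c(res_off, m_off)
  dur <- res_off - res_on
  keep <- dur >= config$min_dur_s - 1e-12 & dur <= config$max_dur_s + 1e-12
  data.frame(onset_s = res_on[keep], offset_s = res_off[keep],
             duration_s = dur[keep])
}

#' Score series to final binary labels
#'
#' Full labeling chain: binarize at the configured threshold, post-process,
#' and return both the event table and the per-sample 0/1 label series.
#'
#' @param score_series Per-sample mean expert scores.
#' @param fs_hz Sampling rate.
#' @param config A [label_config()].
#' @return `list(events, binary_series)`.
#' @export
score_to_labels <- function(score_series, fs_hz, config = label_config()) {
  raw <- moda_binarize(score_series, fs_hz, config$score_threshold)
  ev <- moda_postprocess(raw, config)
  bin <- integer(length(score_series))
  for (i in seq_len(nrow(ev))) {
    a <- floor(ev$onset_s[i] * fs_hz) + 1L
    b <- ceiling(ev$offset_s[i] * fs_hz)
    bin[a:min(b, length(bin))] <- 1L
  }
  list(events = ev, binary_series = bin)
}
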
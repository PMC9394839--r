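# Online stimulation policy and event-level evaluation.
#
# A stimulus is emitted at the first threshold crossing of a detection
# episode; after an episode ends, a refractory timer (400 ms by default)
# suppresses stimuli for episodes that re-start too soon -- those are treated
# as part of the same spindle and restart the timer at their own end.
# Event-level scoring follows the interval definitions: the first stimulus
# landing inside a labeled spindle is its true positive; every other
# stimulus (including early ones) is a false positive; spindles receiving no
# stimulus within their labeled duration are false negatives.

#' Stimulation policy configuration
#'
#' @param threshold Detection cutoff on the detector output; detection is
#'   active while output > threshold (default 0.5).
#' @param refractory_s Refractory period after a detection episode ends
#'   (default 0.4 s).
#' @param budget A [delay_budget()] of constant delays added to trigger
#'   times (64 ms total by default).
#' @param hysteresis Optional margin: an episode ends only when the output
#'   falls below `threshold - hysteresis` (default 0, i.e. off).
#' @return An object of class `"stim_config"`.
#' @export
stim_config <- function(threshold = 0.5, refractory_s = 0.4,
                        budget = delay_budget(), hysteresis = 0) {
  stopifnot(threshold > 0, threshold <= 1, refractory_s >= 0, hysteresis >= 0)
  structure(list(threshold = threshold, refractory_s = refractory_s,
                 budget = budget, hysteresis = hysteresis),
            class = "stim_config")
}

# Detection episodes of an output series: runs of output > threshold (with
# optional hysteresis on the release edge). Returns start/end times, where
# the end is the time of the first forward pass at which the output has
# dropped back below the release level.
detection_episodes <- function(output_series, times, threshold, hysteresis = 0) {
  release <- threshold - hysteresis
  n <- length(output_series)
  starts <- integer(); ends <- integer()
  active <- FALSE
  for (i in seq_len(n)) {
    if (!active && output_series[i] > threshold) {
      active <- TRUE
      starts <- c(starts, i)
    } else if (active && output_series[i] <= release) {
      active <- FALSE
      ends <- c(ends, i)
    }
  }
  if (active) ends <- c(ends, n)
  data.frame(start_t = times[starts], end_t = times[ends])
}

#' Run the stimulation policy over a detector output series
#'
#' @param output_series Detector outputs, one per forward pass.
#' @param times Forward-pass times in seconds (strictly increasing).
#' @param config A [stim_config()].
#' @return Data frame of class `"stim_events"` with `trigger_time_s` (the
#'   threshold-crossing time) and `time_s` (stimulus arrival: trigger plus
#'   the constant delay budget).
#' @export
run_policy <- function(output_series, times, config = stim_config()) {
  stopifnot(length(output_series) == length(times))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  ep <- detection_episodes(output_series, times, config$threshold,
                           config$hysteresis)
  const_s <- total_delay_ms(config$budget) / 1000
  trig <- numeric()
  last_end <- -Inf
  for (i in seq_len(nrow(ep))) {
    if (ep$start_t[i] - last_end >= config$refractory_s) {
      trig <- c(trig, ep$start_t[i])
    }
    # a suppressed episode restarts the timer at its own end
    last_end <- ep$end_t[i]
  }
  structure(data.frame(trigger_time_s = trig, time_s = trig + const_s),
            class = c("stim_events", "data.frame"))
}

#' Event-level scoring of stimuli against labeled spindles
#'
#' For each labeled event `[onset, onset + duration)`, the earliest stimulus
#' whose arrival time lies inside the interval is its true positive (at most
#' one per event); all other stimuli are false positives; events with no
#' in-interval stimulus are false negatives. `delays_s` records, for every
#' event, the arrival time of the closest stimulus minus the event onset
#' (negative when the spindle is stimulated in advance); events are skipped
#' when there is no stimulus at all.
#'
#' @param stimuli A `"stim_events"` data frame from [run_policy()] (or any
#'   data frame with `time_s`).
#' @param events A [spindle_events()] table (non-overlapping).
#' @return `list(tp, fp, fn, precision, recall, f1, delays_s)` of class
#'   `"event_eval"`.
#' @export
score_stimulation <- function(stimuli, events) {
  st <- sort(stimuli$time_s)
  on <- events$onset_s
  off <- events$onset_s + events$duration_s
  n_ev <- length(on)
  if (n_ev > 1) {
    o <- order(on)
    on <- on[o]; off <- off[o]
    if (any(off[-n_ev] > on[-1] + 1e-12)) {
      stop("labeled events must not overlap", call. = FALSE)
    }
  }
  tp_stim <- rep(FALSE, length(st))
  tp <- 0L; fn <- 0L
  delays <- numeric()
  for (i in seq_len(n_ev)) {
    inside <- which(st >= on[i] & st < off[i])
    if (length(inside)) {
      tp <- tp + 1L
      tp_stim[inside[1]] <- TRUE
    } else {
      fn <- fn + 1L
    }
    if (length(st)) {
      delays <- c(delays, st[which.min(abs(st - on[i]))] - on[i])
    }
  }
  fp <- sum(!tp_stim)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, delays_s = delays),
            class = "event_eval")
}

#' @export
print.event_eval <- function(x, ...) {
  cat(sprintf("<event_eval> TP %d, FP %d, FN %d | precision %.3f recall %.3f f1 %.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Sweep the detection threshold
#'
#' Re-runs the full policy and event scoring at each threshold and reports
#' the best-f1 threshold (ties toward the lower threshold).
#'
#' @param output_series,times As in [run_policy()].
#' @param events Labeled [spindle_events()].
#' @param thresholds Threshold grid.
#' @param config Base [stim_config()] supplying refractory and delays.
#' @return `list(curve, best_threshold, best_f1)`; `curve` is a data frame
#'   with one row per threshold (counts, precision, recall, f1, n_stim,
#'   median delay).
#' @export
threshold_sweep <- function(output_series, times, events,
                            thresholds = seq(0.1, 0.95, by = 0.05),
                            config = stim_config()) {
  rows <- lapply(thresholds, function(th) {
    cfg <- config
    cfg$threshold <- th
    stim <- run_policy(output_series, times, cfg)
    ev <- score_stimulation(stim, events)
    data.frame(threshold = th, tp = ev$tp, fp = ev$fp, fn = ev$fn,
               precision = ev$precision, recall = ev$recall, f1 = ev$f1,
               n_stim = nrow(stim),
               median_delay_s = if (length(ev$delays_s)) {
                 median(ev$delays_s)
               } else NA_real_)
  })
  curve <- do.call(rbind, rows)
  i <- which.max(curve$f1)
  list(curve = curve, best_threshold = curve$threshold[i],
       best_f1 = curve$f1[i])
}

#' Summarize stimulation delays
#'
#' Mean, population standard deviation and quantiles of the per-event delays
#' (negative delays retained). An empty result is flagged rather than
#' returning NaNs.
#'
#' @param result An `"event_eval"` from [score_stimulation()].
#' @param probs Quantile probabilities.
#' @return `list(n, mean_s, sd_s, quantiles_s, empty)`.
#' @export
delay_stats <- function(result, probs = c(0.1, 0.25, 0.5, 0.75, 0.9)) {
  d <- result$delays_s
  if (!length(d)) {
    return(list(n = 0L, mean_s = NA_real_, sd_s = NA_real_,
                quantiles_s = setNames(rep(NA_real_, length(probs)),
                                       paste0("q", probs * 100)),
                empty = TRUE))
  }
  list(n = length(d), mean_s = mean(d),
       sd_s = sqrt(mean((d - mean(d))^2)),
       quantiles_s = setNames(quantile(d, probs, names = FALSE),
                              paste0("q", probs * 100)),
       empty = FALSE)
}

#' Fixed band-power baseline detector
#'
#' A heuristic reference: thresholding the (standardized, squared, smoothed)
#' envelope-branch output at a fixed level. Returns a pseudo-output series
#' scaled to `[0, 1]` by `env / (env + level)` so the same policy machinery
#' applies at threshold 0.5 (which corresponds to `env > level`).
#'
#' @param envelope Envelope-branch series.
#' @param level Envelope power level corresponding to detection (default 2:
#'   twice the adapted background level).
#' @return Numeric pseudo-probability series in `[0, 1)`.
#' @export
bandpower_baseline <- function(envelope, level = 2) {
  stopifnot(level > 0)
  envelope / (envelope + level)
}
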
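# Seeded generator of spindle-bearing synthetic EEG.
#
# Emulates consensus-scored polysomnography at desk scale: 12-16 Hz
# Hann-enveloped oscillatory bursts of 0.5-2.5 s superimposed on a 1/f
# background, with a simulated panel of experts producing a per-sample mean
# score. Two cohort profiles are provided: "younger" subjects have more and
# larger spindles than "older" subjects.

#' Synthetic recording configuration
#'
#' Defaults describe the standard study conditions: 500 Hz sampling, spindle
#' oscillation drawn from 12--16 Hz, event durations uniform on 0.5--2.5 s,
#' and an event rate chosen so that about 5% of samples lie inside spindles
#' (2 events/min x 1.5 s mean duration = 5% for the younger cohort).
#'
#' @param fs_hz Sampling rate (default 500; must exceed twice the top of
#'   `freq_range_hz`).
#' @param duration_s Total recording length in seconds.
#' @param cohort `"younger"` (default) or `"older"`. The older profile has a
#'   lower event rate and lower burst amplitudes.
#' @param spindle_rate_per_min Events per minute; default 2 for younger,
#'   1.4 for older.
#' @param freq_range_hz Spindle oscillation band (default `c(12, 16)`).
#' @param dur_range_s Event duration range (default `c(0.5, 2.5)`).
#' @param amp_mean_uv Median peak burst amplitude in microvolts; default 30
#'   (younger) or 15 (older). Per-event amplitudes are log-normal around this
#'   with log-sd `amp_sdlog`.
#' @param amp_sdlog Log-sd of the per-event amplitude distribution (0.2).
#' @param noise_rms_uv RMS of the 1/f background (default 10).
#' @param noise_exponent Background spectral slope: power ~ 1/f^exponent
#'   (default 1).
#' @param mains_hz `"none"` (default), 50 or 60: optional hum sinusoid.
#' @param mains_amp_uv Hum amplitude in microvolts.
#' @param n_experts Simulated annotator count (default 5).
#' @param expert_slope,expert_midpoint Parameters of the per-expert detection
#'   probability, logistic in log signal-to-noise ratio:
#'   `p = plogis(expert_slope * (log(amp / noise_rms_uv) - log(expert_midpoint)))`.
#'   A zero-amplitude event has probability exactly 0.
#' @param min_gap_s Minimum gap enforced between events (default 0.4 s, so
#'   downstream refractory logic is exercised but events stay separable).
#' @param seed RNG seed.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(fs_hz = 500, duration_s = 1800,
                         cohort = c("younger", "older"),
                         spindle_rate_per_min = NULL,
                         freq_range_hz = c(12, 16),
                         dur_range_s = c(0.5, 2.5),
                         amp_mean_uv = NULL, amp_sdlog = 0.2,
                         noise_rms_uv = 10, noise_exponent = 1,
                         mains_hz = "none", mains_amp_uv = 2,
                         n_experts = 5, expert_slope = 3,
                         expert_midpoint = 0.8, min_gap_s = 0.4, seed = 1) {
  cohort <- match.arg(cohort)
  spindle_rate_per_min <- spindle_rate_per_min %||%
    switch(cohort, younger = 2, older = 1.4)
  amp_mean_uv <- amp_mean_uv %||% switch(cohort, younger = 30, older = 15)
  stopifnot(fs_hz > 2 * max(freq_range_hz),
            dur_range_s[1] > 0, dur_range_s[2] <= duration_s,
            dur_range_s[1] <= dur_range_s[2],
            spindle_rate_per_min >= 0, n_experts >= 1)
  if (!identical(mains_hz, "none")) {
    mains_hz <- as.numeric(mains_hz)
    stopifnot(mains_hz %in% c(50, 60))
  }
  structure(list(
    fs_hz = fs_hz, duration_s = duration_s, cohort = cohort,
    spindle_rate_per_min = spindle_rate_per_min,
    freq_range_hz = freq_range_hz, dur_range_s = dur_range_s,
    amp_mean_uv = amp_mean_uv, amp_sdlog = amp_sdlog,
    noise_rms_uv = noise_rms_uv, noise_exponent = noise_exponent,
    mains_hz = mains_hz, mains_amp_uv = mains_amp_uv,
    n_experts = n_experts, expert_slope = expert_slope,
    expert_midpoint = expert_midpoint, min_gap_s = min_gap_s, seed = seed
  ), class = "synth_config")
}

# 1/f^exponent background noise via spectral shaping of white noise,
# scaled to the requested RMS. Deterministic under the caller's RNG state.
pink_noise <- function(n, exponent, rms) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))              # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)                # two-sided frequency index
  shape <- 1 / f^(exponent / 2)
  shape[1] <- 0                          # remove DC
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x * rms / sqrt(mean(x^2))
}

# Place n events of given durations with gaps >= min_gap (also from the
# edges), by distributing the free time randomly among the n + 1 gaps.
place_events <- function(durations, total_s, min_gap) {
  n <- length(durations)
  if (n == 0L) return(numeric())
  free <- total_s - sum(durations) - (n + 1) * min_gap
  if (free < 0) {
    stop("expected event span exceeds recording duration: lower the rate or ",
         "shorten durations", call. = FALSE)
  }
  u <- runif(n + 1)
  gaps <- min_gap + free * u / sum(u)
  onsets <- numeric(n)
  t <- 0
  for (i in seq_len(n)) {
    t <- t + gaps[i]
    onsets[i] <- t
    t <- t + durations[i]
  }
  onsets
}

#' Simulate a panel of expert scores for placed events
#'
#' Each of `n_experts` virtual annotators independently marks an event with a
#' probability that increases with the event's amplitude signal-to-noise
#' ratio (logistic in log-SNR, so a zero-amplitude event is never marked).
#' The per-sample score is the fraction of experts marking, held constant
#' over the event interval and 0 elsewhere.
#'
#' @param events Data frame with `onset_s`, `duration_s`, `amp_uv`.
#' @param n_samples Length of the output series.
#' @param fs_hz Sampling rate.
#' @param noise_rms_uv Background RMS used in the SNR.
#' @param n_experts Number of simulated annotators.
#' @param slope,midpoint Logistic parameters (see [synth_config()]).
#' @param prob Optional fixed per-expert detection probability overriding the
#'   amplitude model (scalar or per-event vector).
#' @param seed RNG seed.
#' @return `list(score_series, event_scores, detect_prob)`.
#' @export
simulate_expert_scores <- function(events, n_samples, fs_hz, noise_rms_uv,
                                   n_experts = 5, slope = 3, midpoint = 0.8,
                                   prob = NULL, seed = 1) {
  stopifnot(n_experts >= 1)
  n_ev <- nrow(events)
  p <- if (!is.null(prob)) {
    rep_len(prob, n_ev)
  } else {
    snr <- events$amp_uv / noise_rms_uv
    plogis(slope * (log(snr) - log(midpoint)))  # log(0) = -Inf -> p = 0
  }
  scores <- with_seed(seed, rbinom(n_ev, n_experts, p) / n_experts)
  series <- numeric(n_samples)
  for (i in seq_len(n_ev)) {
    a <- floor(events$onset_s[i] * fs_hz) + 1L
    b <- ceiling((events$onset_s[i] + events$duration_s[i]) * fs_hz)
    series[a:min(b, n_samples)] <- scores[i]
  }
  list(score_series = series, event_scores = scores, detect_prob = p)
}

#' Generate a synthetic recording with ground truth
#'
#' Deterministic for a fixed seed. The number of events is
#' `round(rate * duration / 60)`; their oscillation frequency is drawn per
#' event from `freq_range_hz`, the amplitude envelope is a Hann window over
#' the event duration, and events are separated by at least `min_gap_s`.
#' Ground-truth binary labels are derived from the simulated expert scores by
#' the standard label chain ([score_to_labels()]) at the cohort's threshold.
#'
#' @param config A [synth_config()].
#' @return `list(recording, ground_truth)` where `ground_truth` has `events`
#'   (a [spindle_events()] table after post-processing), `placed_events`
#'   (all generated bursts with amplitudes), `score_series` and
#'   `binary_series` (per sample at `fs_hz`).
#' @export
#' @examples
#' out <- generate_recording(synth_config(duration_s = 60, seed = 7))
#' out$recording
#' nrow(out$ground_truth$events)
generate_recording <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- round(config$fs_hz * config$duration_s)
  with_seed(config$seed, {
    n_ev <- round(config$spindle_rate_per_min * config$duration_s / 60)
    durations <- runif(n_ev, config$dur_range_s[1], config$dur_range_s[2])
    onsets <- place_events(durations, config$duration_s, config$min_gap_s)
    freqs <- runif(n_ev, config$freq_range_hz[1], config$freq_range_hz[2])
    amps <- rlnorm(n_ev, log(config$amp_mean_uv), config$amp_sdlog)
    phases <- runif(n_ev, 0, 2 * pi)
    x <- pink_noise(n, config$noise_exponent, config$noise_rms_uv)
    if (!identical(config$mains_hz, "none")) {
      t_all <- (seq_len(n) - 1) / config$fs_hz
      x <- x + config$mains_amp_uv * sin(2 * pi * config$mains_hz * t_all)
    }
    for (i in seq_len(n_ev)) {
      a <- floor(onsets[i] * config$fs_hz) + 1L
      b <- min(ceiling((onsets[i] + durations[i]) * config$fs_hz), n)
      k <- b - a + 1L
      t_ev <- (seq_len(k) - 1) / config$fs_hz
      env <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = k)))
      x[a:b] <- x[a:b] +
        amps[i] * env * sin(2 * pi * freqs[i] * t_ev + phases[i])
    }
    placed <- data.frame(onset_s = onsets, duration_s = durations,
                         freq_hz = freqs, amp_uv = amps)
    sc <- simulate_expert_scores(
      placed, n, config$fs_hz, config$noise_rms_uv,
      n_experts = config$n_experts, slope = config$expert_slope,
      midpoint = config$expert_midpoint,
      seed = derive_seed(config$seed, "experts")
    )
    lab <- score_to_labels(sc$score_series, config$fs_hz,
                           label_config(cohort_threshold(config$cohort)))
    ev_scores <- vapply(seq_len(nrow(lab$events)), function(i) {
      a <- floor(lab$events$onset_s[i] * config$fs_hz) + 2L
      sc$score_series[min(a, n)]
    }, numeric(1))
    rec <- eeg_recording(x, config$fs_hz,
                         subject_id = sprintf("SYN%04d", config$seed %% 10000),
                         cohort = config$cohort)
    list(
      recording = rec,
      ground_truth = list(
        events = spindle_events(lab$events$onset_s, lab$events$duration_s,
                                ev_scores),
        placed_events = placed,
        score_series = sc$score_series,
        binary_series = lab$binary_series
      )
    )
  })
}
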
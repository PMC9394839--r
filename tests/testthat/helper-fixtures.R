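# Shared fixtures and independent oracles used across test files.

# Small detector config whose parameter count is hand-checkable and whose
# training runs in seconds.
toy_detector_config <- function(dilation_k = 2, output_head = "classifier") {
  detector_config(
    window_samples = 32, stride_samples = 5,
    conv_blocks = list(c(4, 7, 2)), gru_hidden = 8, gru_layers = 1,
    dilation_k = dilation_k, output_head = output_head
  )
}

# Alternating noise / pure 14 Hz burst segments at 250 Hz: a (nearly)
# linearly separable toy problem for training sanity checks.
separable_toy <- function(n_seg = 60, seg_s = 2, fs = 250, seed = 3) {
  withr::with_seed(seed, {
    seg <- seg_s * fs
    lab <- rep(rep(c(0L, 1L), n_seg / 2), each = seg)
    x <- numeric(n_seg * seg)
    for (i in seq_len(n_seg)) {
      idx <- ((i - 1) * seg + 1):(i * seg)
      x[idx] <- if (i %% 2 == 0) {
        2 * sin(2 * pi * 14 * (idx / fs)) + 0.2 * rnorm(seg)
      } else {
        rnorm(seg)
      }
    }
    list(x = x, labels = lab, fs = fs)
  })
}

# Independent brute-force oracle for event-level stimulation scoring:
# literal transcription of the interval definitions, no shared code with
# score_stimulation().
oracle_event_score <- function(stim_times, onsets, offsets) {
  st <- sort(stim_times)
  used <- rep(FALSE, length(st))
  tp <- 0L; fn <- 0L
  for (i in seq_along(onsets)) {
    inside <- which(st >= onsets[i] & st < offsets[i])
    if (length(inside)) {
      tp <- tp + 1L
      used[inside[1]] <- TRUE
    } else {
      fn <- fn + 1L
    }
  }
  list(tp = tp, fp = sum(!used), fn = fn)
}

# Random non-overlapping event layout on [0, total_s].
random_events <- function(n_ev, total_s, seed) {
  withr::with_seed(seed, {
    dur <- runif(n_ev, 0.5, 2.5)
    gaps <- runif(n_ev + 1)
    free <- total_s - sum(dur) - 0.5 * (n_ev + 1)
    gaps <- 0.5 + free * gaps / sum(gaps)
    on <- cumsum(gaps)[seq_len(n_ev)] + cumsum(c(0, dur[-n_ev]))
    spindle_events(on, dur, rep(0.8, n_ev))
  })
}

# Replay a sample vector through the preprocessing pipeline in random-sized
# chunks; returns both branch outputs.
chunked_preprocess <- function(x, config, chunk_sizes) {
  st <- pipeline_init(config)
  clean <- numeric(); env <- numeric()
  idx <- 1L
  for (k in chunk_sizes) {
    if (idx > length(x)) break
    r <- preprocess_chunks(st, x[idx:min(idx + k - 1L, length(x))])
    st <- r$state
    clean <- c(clean, r$clean); env <- c(env, r$envelope)
    idx <- idx + k
  }
  if (idx <= length(x)) {
    r <- preprocess_chunks(st, x[idx:length(x)])
    clean <- c(clean, r$clean); env <- c(env, r$envelope)
  }
  list(clean = clean, envelope = env)
}

# Steady-state amplitude gain of a causal scalar transform at one frequency,
# measured over the last second of a sine of length `dur_s`.
sine_gain <- function(transform, f_hz, fs, dur_s = 30, amp = 1) {
  t <- (0:(dur_s * fs - 1)) / fs
  y <- transform(amp * sin(2 * pi * f_hz * t))
  tail_idx <- (length(y) - fs + 1):length(y)
  # amplitude estimate robust to phase: sqrt(2) * RMS
  sqrt(2 * mean(y[tail_idx]^2)) / amp
}
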
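# Streaming two-branch preprocessing pipeline.
#
# All operations are causal and chunk-transparent: processing a signal in
# arbitrary chunks produces bit-identical output to processing it whole,
# because every stage carries its exact filter/EMA state across chunk
# boundaries and performs the same floating-point operations in the same
# order either way.

#' FIR filter specification
#'
#' Linear-phase FIR specifications for the two preprocessing branches.
#' `order` must be even so the group delay (`order / 2` samples) is an integer
#' number of samples, which keeps the delay bookkeeping exact.
#'
#' @param kind `"bandpass_fir"` or `"notch"`.
#' @param order Filter order (taps - 1); must be even. Default 20.
#' @param band_hz Length-2 passband `[low, high]` in Hz (band-pass only).
#' @param notch_hz Mains frequency to reject, 50 or 60 (notch only).
#' @param fs_hz Operating sampling rate in Hz.
#' @param notch_halfwidth_hz Half-width of the notch stop band (default 5 Hz).
#' @return An object of class `"filter_spec"`.
#' @export
#' @examples
#' taps <- design_fir(filter_spec("bandpass_fir", band_hz = c(0.5, 30)))
#' length(taps) # 21
filter_spec <- function(kind = c("bandpass_fir", "notch"), order = 20,
                        band_hz = c(0.5, 30), notch_hz = 50, fs_hz = 250,
                        notch_halfwidth_hz = 5) {
  kind <- match.arg(kind)
  stop_if_not_scalar_number(order, "order")
  stop_if_not_scalar_number(fs_hz, "fs_hz")
  if (order %% 2 != 0) {
    stop("FIR `order` must be even (integer-sample group delay)", call. = FALSE)
  }
  if (kind == "bandpass_fir") {
    stopifnot(length(band_hz) == 2)
    if (!(0 < band_hz[1] && band_hz[1] < band_hz[2] && band_hz[2] < fs_hz / 2)) {
      stop("need 0 < low < high < fs_hz / 2", call. = FALSE)
    }
  } else {
    if (!notch_hz %in% c(50, 60)) stop("notch_hz must be 50 or 60", call. = FALSE)
    if (notch_hz + notch_halfwidth_hz >= fs_hz / 2) {
      stop("notch stop band exceeds Nyquist", call. = FALSE)
    }
  }
  structure(list(kind = kind, order = order, band_hz = band_hz,
                 notch_hz = notch_hz, fs_hz = fs_hz,
                 notch_halfwidth_hz = notch_halfwidth_hz),
            class = "filter_spec")
}

#' Design a linear-phase FIR filter
#'
#' Windowed-sinc (Hamming) design via [signal::fir1()]. The returned taps are
#' symmetric, so the filter is exactly linear-phase with group delay
#' `order / 2` samples at every frequency.
#'
#' @param spec A [filter_spec()].
#' @return Numeric vector of `order + 1` taps.
#' @export
design_fir <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  nyq <- spec$fs_hz / 2
  taps <- if (spec$kind == "bandpass_fir") {
    signal::fir1(spec$order, spec$band_hz / nyq, type = "pass")
  } else {
    w <- spec$notch_halfwidth_hz
    signal::fir1(spec$order, c(spec$notch_hz - w, spec$notch_hz + w) / nyq,
                 type = "stop")
  }
  as.numeric(taps)
}

# ---- streaming primitives ---------------------------------------------------

#' Streaming FIR filter state
#'
#' `fir_init()` creates the delay line; `fir_apply()` filters a chunk and
#' returns the updated state. Chunk boundaries do not affect the output.
#'
#' @param taps FIR coefficient vector.
#' @return `fir_init()`: a state list; `fir_apply()`: `list(state, y)`.
#' @export
fir_init <- function(taps) {
  list(taps = as.numeric(taps), buf = numeric(length(taps) - 1L))
}

#' @param state State from [fir_init()] (possibly updated by earlier calls).
#' @param x Numeric chunk of input samples.
#' @rdname fir_init
#' @export
fir_apply <- function(state, x) {
  x <- as.numeric(x)
  n <- length(x)
  if (!n) return(list(state = state, y = numeric()))
  taps <- state$taps
  m <- length(taps) - 1L
  xext <- c(state$buf, x)
  # y[i] = sum_k taps[k + 1] * xext[m + i - k]; fixed summation order over k
  # makes chunked and whole-signal runs bit-identical.
  y <- numeric(n)
  for (k in 0:m) {
    y <- y + taps[k + 1L] * xext[(m + 1L - k):(m + n - k)]
  }
  state$buf <- xext[(n + 1L):(n + m)]
  list(state = state, y = y)
}

#' Running-mean high-pass
#'
#' The high-pass implied by online standardization: `x - mu` where
#' `mu_n = (1 - alpha) mu_{n-1} + alpha x_n`. With `alpha = 0.1` at 250 Hz its
#' -3 dB cutoff sits near 4.7 Hz, so everything below 4 Hz is attenuated by
#' more than 3 dB.
#'
#' @param x Input samples.
#' @param alpha EMA coefficient in (0, 1].
#' @param mu0 Initial mean estimate (default: first sample).
#' @return Numeric vector `x - mu`.
#' @export
running_mean_highpass <- function(x, alpha, mu0 = NULL) {
  x <- as.numeric(x)
  if (!length(x)) return(numeric())
  mu0 <- mu0 %||% x[1]
  mu <- as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                                 init = mu0))
  x - mu
}

#' Online exponential-moving-average standardizer
#'
#' Causal, O(1)-memory standardization: `mu` tracks the mean with coefficient
#' `alpha_mu`, `v` tracks the variance of the mean-removed signal with
#' coefficient `alpha_sigma` (using the post-update mean), and the output is
#' `(x - mu) / sqrt(v + eps)`. State is initialized at the first sample with
#' `mu = x[1]`, `v = 1` to avoid start-up spikes.
#'
#' @param alpha_mu Running-mean coefficient in (0, 1].
#' @param alpha_sigma Running-variance coefficient in (0, 1].
#' @param eps Variance floor (default 1e-8).
#' @return `standardizer_init()`: a state list; `standardize_apply()`:
#'   `list(state, y)`.
#' @export
standardizer_init <- function(alpha_mu, alpha_sigma, eps = 1e-8) {
  stopifnot(alpha_mu > 0, alpha_mu <= 1, alpha_sigma > 0, alpha_sigma <= 1)
  list(alpha_mu = alpha_mu, alpha_sigma = alpha_sigma, eps = eps,
       mu = NA_real_, v = 1, started = FALSE)
}

#' @param state State from [standardizer_init()].
#' @param x Numeric chunk.
#' @rdname standardizer_init
#' @export
standardize_apply <- function(state, x) {
  x <- as.numeric(x)
  if (!length(x)) return(list(state = state, y = numeric()))
  if (!state$started) {
    state$mu <- x[1]
    state$started <- TRUE
  }
  mu <- as.numeric(stats::filter(state$alpha_mu * x, 1 - state$alpha_mu,
                                 method = "recursive", init = state$mu))
  d <- x - mu
  v <- as.numeric(stats::filter(state$alpha_sigma * d^2, 1 - state$alpha_sigma,
                                method = "recursive", init = state$v))
  y <- d / sqrt(v + state$eps)
  state$mu <- mu[length(mu)]
  state$v <- v[length(v)]
  list(state = state, y = y)
}

#' Streaming EMA smoother
#'
#' First-order exponential smoothing `s_n = (1 - alpha) s_{n-1} + alpha x_n`
#' with initial state 0 (so an all-zero input yields an all-zero output).
#'
#' @param alpha Smoothing coefficient in (0, 1].
#' @return `ema_init()`: a state list; `ema_apply()`: `list(state, y)`.
#' @export
ema_init <- function(alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  list(alpha = alpha, s = 0)
}

#' @param state State from [ema_init()].
#' @param x Numeric chunk.
#' @rdname ema_init
#' @export
ema_apply <- function(state, x) {
  x <- as.numeric(x)
  if (!length(x)) return(list(state = state, y = numeric()))
  y <- as.numeric(stats::filter(state$alpha * x, 1 - state$alpha,
                                method = "recursive", init = state$s))
  state$s <- y[length(y)]
  list(state = state, y = y)
}

#' Streaming 2:1 downsampler
#'
#' Anti-alias low-pass (linear-phase FIR, cutoff 100 Hz at the default raw
#' rate of 500 Hz) followed by decimation keeping sample index 0, 2, 4, ...
#' A length-`N` input yields `ceiling(N / 2)` output samples.
#'
#' @param fs_raw Input sampling rate (Hz).
#' @param factor Decimation factor (default 2).
#' @param aa_order Anti-alias FIR order (even; default 30).
#' @return `downsampler_init()`: a state list; `downsample_apply()`:
#'   `list(state, y)`.
#' @export
downsampler_init <- function(fs_raw = 500, factor = 2L, aa_order = 30) {
  stopifnot(factor >= 1, aa_order %% 2 == 0)
  cutoff <- 0.8 * (fs_raw / factor / 2)
  taps <- as.numeric(signal::fir1(aa_order, cutoff / (fs_raw / 2)))
  list(fir = fir_init(taps), factor = as.integer(factor), phase = 0L)
}

#' @param state State from [downsampler_init()].
#' @param x Numeric chunk at the raw rate.
#' @rdname downsampler_init
#' @export
downsample_apply <- function(state, x) {
  x <- as.numeric(x)
  if (!length(x)) return(list(state = state, y = numeric()))
  res <- fir_apply(state$fir, x)
  state$fir <- res$state
  idx_global <- state$phase + seq_along(x) - 1L
  keep <- idx_global %% state$factor == 0L
  state$phase <- (state$phase + length(x)) %% state$factor
  list(state = state, y = res$y[keep])
}

# ---- pipeline ---------------------------------------------------------------

#' Preprocessing pipeline configuration
#'
#' Defaults follow the closed-loop EEG front end: acquire at 500 Hz,
#' downsample to 250 Hz, optionally notch-filter mains hum, then split into a
#' cleaned-signal branch (order-20 FIR 0.5--30 Hz, standardize with
#' `alpha_mu = 0.1`, `alpha_sigma = 0.001`) and an envelope branch (order-20
#' FIR 12--16 Hz, standardize with `alpha_mu = alpha_sigma = 0.001`, square,
#' smooth with `alpha = 0.01`). With order-20 FIRs at 250 Hz each branch adds
#' exactly 10 samples = 40 ms of constant software delay.
#'
#' @param fs_raw Acquisition rate in Hz (default 500).
#' @param fs_proc Processing rate in Hz (default 250). If equal to `fs_raw`,
#'   no downsampling is performed.
#' @param mains_hz `"none"`, `50`, or `60`: mains notch applied to the common
#'   path before the branch split (so both branches stay delay-matched).
#' @param fir_order Order of the branch FIRs (even; default 20).
#' @param clean_band_hz Cleaned-branch passband (default `c(0.5, 30)`).
#' @param envelope_band_hz Envelope-branch passband (default `c(12, 16)`).
#' @param alpha_mu_clean,alpha_sigma_clean Cleaned-branch standardizer
#'   coefficients (defaults 0.1, 0.001).
#' @param alpha_mu_env,alpha_sigma_env Envelope-branch standardizer
#'   coefficients (defaults 0.001, 0.001).
#' @param alpha_smooth Envelope smoother coefficient (default 0.01).
#' @return An object of class `"preproc_config"`.
#' @export
preproc_config <- function(fs_raw = 500, fs_proc = 250, mains_hz = "none",
                           fir_order = 20, clean_band_hz = c(0.5, 30),
                           envelope_band_hz = c(12, 16),
                           alpha_mu_clean = 0.1, alpha_sigma_clean = 0.001,
                           alpha_mu_env = 0.001, alpha_sigma_env = 0.001,
                           alpha_smooth = 0.01) {
  if (!identical(mains_hz, "none")) {
    mains_hz <- as.numeric(mains_hz)
    if (!mains_hz %in% c(50, 60)) stop("mains_hz must be 'none', 50 or 60", call. = FALSE)
  }
  stopifnot(fs_raw >= fs_proc, fs_raw %% fs_proc == 0)
  structure(list(
    fs_raw = fs_raw, fs_proc = fs_proc, mains_hz = mains_hz,
    fir_order = fir_order, clean_band_hz = clean_band_hz,
    envelope_band_hz = envelope_band_hz,
    alpha_mu_clean = alpha_mu_clean, alpha_sigma_clean = alpha_sigma_clean,
    alpha_mu_env = alpha_mu_env, alpha_sigma_env = alpha_sigma_env,
    alpha_smooth = alpha_smooth
  ), class = "preproc_config")
}

#' Constant per-branch software delay
#'
#' Each branch FIR is linear-phase of even order, so the branch delay is
#' exactly `fir_order / 2` samples at the processing rate.
#'
#' @param config A [preproc_config()].
#' @return `branch_delay_samples()`: delay in samples;
#'   `branch_delay_ms()`: the same in milliseconds.
#' @export
branch_delay_samples <- function(config) config$fir_order / 2

#' @rdname branch_delay_samples
#' @export
branch_delay_ms <- function(config) {
  1000 * branch_delay_samples(config) / config$fs_proc
}

#' Initialize the streaming preprocessing state
#'
#' @param config A [preproc_config()].
#' @return A pipeline state for [preprocess_chunks()].
#' @export
pipeline_init <- function(config = preproc_config()) {
  stopifnot(inherits(config, "preproc_config"))
  factor <- config$fs_raw / config$fs_proc
  notch <- NULL
  if (!identical(config$mains_hz, "none")) {
    notch <- fir_init(design_fir(filter_spec(
      "notch", order = config$fir_order, notch_hz = config$mains_hz,
      fs_hz = config$fs_proc
    )))
  }
  list(
    config = config,
    down = if (factor > 1) downsampler_init(config$fs_raw, factor) else NULL,
    notch = notch,
    clean_fir = fir_init(design_fir(filter_spec(
      "bandpass_fir", order = config$fir_order,
      band_hz = config$clean_band_hz, fs_hz = config$fs_proc
    ))),
    clean_std = standardizer_init(config$alpha_mu_clean, config$alpha_sigma_clean),
    env_fir = fir_init(design_fir(filter_spec(
      "bandpass_fir", order = config$fir_order,
      band_hz = config$envelope_band_hz, fs_hz = config$fs_proc
    ))),
    env_std = standardizer_init(config$alpha_mu_env, config$alpha_sigma_env),
    env_smooth = ema_init(config$alpha_smooth)
  )
}

#' Process a chunk through both preprocessing branches
#'
#' Downsamples (if configured), applies the optional common notch, then the
#' cleaned-signal and envelope branches. Output is aligned at the processing
#' rate; both branches have identical constant delay.
#'
#' @param state Pipeline state from [pipeline_init()].
#' @param x Raw samples at `fs_raw`.
#' @return `list(state, clean, envelope)`; the two series have equal length.
#' @export
preprocess_chunks <- function(state, x) {
  if (!is.null(state$down)) {
    r <- downsample_apply(state$down, x); state$down <- r$state; x <- r$y
  }
  if (!is.null(state$notch)) {
    r <- fir_apply(state$notch, x); state$notch <- r$state; x <- r$y
  }
  r <- fir_apply(state$clean_fir, x); state$clean_fir <- r$state
  r <- standardize_apply(state$clean_std, r$y); state$clean_std <- r$state
  clean <- r$y
  r <- fir_apply(state$env_fir, x); state$env_fir <- r$state
  r <- standardize_apply(state$env_std, r$y); state$env_std <- r$state
  r <- ema_apply(state$env_smooth, r$y^2); state$env_smooth <- r$state
  list(state = state, clean = clean, envelope = r$y)
}

#' Preprocess a whole recording
#'
#' Convenience wrapper running [preprocess_chunks()] once over the full
#' sample vector (identical to any chunked replay).
#'
#' @param rec An [eeg_recording()] at `config$fs_raw`.
#' @param config A [preproc_config()].
#' @return `list(clean, envelope, fs_hz, delay_ms)`.
#' @export
preprocess_recording <- function(rec, config = preproc_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (abs(rec$fs_hz - config$fs_raw) > 1e-9) {
    stop(sprintf("recording is at %g Hz but config$fs_raw is %g Hz",
                 rec$fs_hz, config$fs_raw), call. = FALSE)
  }
  out <- preprocess_chunks(pipeline_init(config), rec$samples)
  list(clean = out$clean, envelope = out$envelope, fs_hz = config$fs_proc,
       delay_ms = branch_delay_ms(config))
}

#' Hardware/software delay budget
#'
#' Constant delays added between a threshold crossing of the detector output
#' and the arrival of the stimulus: the FIR branch group delay, the detector
#' forward-pass duration, and the stimulus output latency.
#'
#' @param filter_ms FIR branch software delay (default 40 ms).
#' @param ann_ms Detector forward-pass hardware delay (default 20 ms).
#' @param stim_ms Stimulus output delay (default 4 ms).
#' @return An object of class `"delay_budget"`; `total_delay_ms()` gives the
#'   summed constant delay (64 ms with defaults).
#' @export
delay_budget <- function(filter_ms = 40, ann_ms = 20, stim_ms = 4) {
  stopifnot(filter_ms >= 0, ann_ms >= 0, stim_ms >= 0)
  structure(list(filter_ms = filter_ms, ann_ms = ann_ms, stim_ms = stim_ms),
            class = "delay_budget")
}

#' @param budget A [delay_budget()].
#' @rdname delay_budget
#' @export
total_delay_ms <- function(budget) {
  budget$filter_ms + budget$ann_ms + budget$stim_ms
}
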
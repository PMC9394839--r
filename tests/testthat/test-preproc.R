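# Streaming preprocessing: FIR design, delays, online standardization,
# envelope extraction, downsampling, and the chunk-transparency contract.

test_that("order-20 band-pass is linear-phase with 10 samples group delay", {
  taps <- design_fir(filter_spec("bandpass_fir", order = 20,
                                 band_hz = c(0.5, 30), fs_hz = 250))
  expect_length(taps, 21)
  expect_lt(max(abs(taps - rev(taps))), 1e-14)  # symmetric taps
  # impulse response: cross-correlation peak between input and output
  x <- c(1, numeric(99))
  st <- fir_init(taps)
  y <- fir_apply(st, x)$y
  lags <- 0:30
  cc <- vapply(lags, function(L) sum(x[seq_len(100 - L)] * y[seq_len(100 - L) + L]),
               numeric(1))
  delay <- lags[which.max(cc)]
  expect_identical(delay, 10L)
  expect_equal(1000 * delay / 250, 40)  # ms
})

test_that("impulse response equals the coefficient sequence", {
  taps <- design_fir(filter_spec("bandpass_fir", band_hz = c(12, 16)))
  y <- fir_apply(fir_init(taps), c(1, numeric(20)))$y
  expect_equal(y, taps)
})

test_that("the clean-band design attenuates 40 Hz relative to 15 Hz", {
  taps <- design_fir(filter_spec("bandpass_fir", band_hz = c(0.5, 30)))
  gain <- function(f) Mod(sum(taps * exp(-1i * 2 * pi * f / 250 * (0:20))))
  expect_lt(gain(40), gain(15))
  expect_lt(gain(40) / gain(15), 0.2)
})

test_that("odd filter orders are rejected", {
  expect_error(filter_spec("bandpass_fir", order = 21), "even")
})

test_that("standardizer output converges to zero on constant input", {
  st <- standardizer_init(0.1, 0.001)
  y <- standardize_apply(st, rep(7.3, 5000))$y
  expect_lt(abs(tail(y, 1)), 1e-10)
})

test_that("standardizer output variance approaches 1 on white noise", {
  x <- withr::with_seed(11, rnorm(2e5))
  y <- standardize_apply(standardizer_init(0.1, 0.001), x)$y
  expect_lt(abs(var(y[-(1:5000)]) - 1), 0.1)
})

test_that("running-mean high-pass attenuates below 4 Hz by more than 3 dB", {
  # sine-sweep oracle on the (x - running mean) transform, alpha 0.1, 250 Hz
  fs <- 250
  gains <- vapply(seq(0.5, 10, by = 0.25), function(f) {
    sine_gain(function(x) running_mean_highpass(x, 0.1), f, fs)
  }, numeric(1))
  freqs <- seq(0.5, 10, by = 0.25)
  below4 <- gains[freqs < 4]
  expect_true(all(below4 < 10^(-3 / 20)))
  # computed -3 dB point sits near 4.7 Hz
  f3 <- freqs[which.min(abs(gains - 10^(-3 / 20)))]
  expect_gt(f3, 4)
  expect_lt(f3, 5.5)
})

test_that("mains hum is strongly attenuated by the cleaned branch", {
  fs <- 250
  cfg <- preproc_config(fs_raw = fs, fs_proc = fs, mains_hz = 50)
  run_branch <- function(f_hz) {
    t <- (0:(fs * 30 - 1)) / fs
    x <- 10 * sin(2 * pi * f_hz * t)
    st <- pipeline_init(cfg)
    # measure at the FIR cascade output (before standardization, which
    # rescales any steady tone): notch then band-pass
    r1 <- fir_apply(st$notch, x)$y
    r2 <- fir_apply(st$clean_fir, r1)$y
    sqrt(2 * mean(tail(r2, fs)^2))
  }
  att_db <- 20 * log10(run_branch(50) / run_branch(10))
  expect_lt(att_db, -20)
})

test_that("zero input produces zero output in both branches", {
  st <- pipeline_init(preproc_config(fs_raw = 250, fs_proc = 250))
  r <- preprocess_chunks(st, numeric(2000))
  expect_true(all(r$clean == 0))
  expect_true(all(r$envelope == 0))
})

test_that("envelope is nonnegative and responds to in-band bursts", {
  fs <- 250
  cfg <- preproc_config(fs_raw = fs, fs_proc = fs)
  burst_response <- function(burst_hz, seed = 5) {
    withr::with_seed(seed, {
      bg <- rnorm(60 * fs, sd = 10)
      env_w <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = 2 * fs)))
      t_b <- (0:(2 * fs - 1)) / fs
      burst <- 30 * sin(2 * pi * burst_hz * t_b) * env_w
      x <- c(bg, bg[seq_len(2 * fs)] + burst, rnorm(5 * fs, sd = 10))
      r <- preprocess_chunks(pipeline_init(cfg), x)
      list(env = r$envelope,
           baseline = mean(r$envelope[(55 * fs):(60 * fs)]),
           peak = max(r$envelope[(60 * fs + 1):(63 * fs)]))
    })
  }
  b14 <- burst_response(14)
  b5 <- burst_response(5)
  expect_true(all(b14$env >= 0))
  # a spindle-band burst lifts the envelope far above the adapted background
  expect_gt(b14$peak / b14$baseline, 5)
  # and more than an equal-amplitude out-of-band burst (limited by the
  # short order-20 FIR's 5 Hz rejection; bound frozen from the measured
  # oracle ratio of ~1.30)
  expect_gt(b14$peak / b5$peak, 1.15)
})

test_that("downsampler preserves a 10 Hz tone and halves the length", {
  fs <- 500
  t <- (0:(fs * 10 - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  r <- downsample_apply(downsampler_init(fs, 2L), x)
  expect_length(r$y, ceiling(length(x) / 2))
  amp <- sqrt(2 * mean(tail(r$y, 250)^2))
  expect_lt(abs(amp - 1), 0.01)
  # constant in, same constant out within the FIR's passband ripple (<1%)
  rc <- downsample_apply(downsampler_init(fs, 2L), rep(3, 1000))
  expect_lt(max(abs(tail(rc$y, 400) - 3)), 0.03)
  # odd lengths round up
  r3 <- downsample_apply(downsampler_init(fs, 2L), rnorm(7))
  expect_length(r3$y, 4)
})

test_that("chunked and whole-signal processing are bit-identical", {
  x <- withr::with_seed(21, rnorm(20000, sd = 20))
  cfg <- preproc_config()  # includes the 500 -> 250 Hz downsampler
  whole <- preprocess_chunks(pipeline_init(cfg), x)
  for (seed in 1:5) {
    sizes <- withr::with_seed(seed, sample(c(1, 2, 3, 7, 50, 333, 1000),
                                           200, replace = TRUE))
    ch <- chunked_preprocess(x, cfg, sizes)
    expect_identical(ch$clean, whole$clean)
    expect_identical(ch$envelope, whole$envelope)
  }
})

test_that("both branches report the same constant 40 ms delay", {
  cfg <- preproc_config()
  expect_identical(branch_delay_samples(cfg), 10)
  expect_identical(branch_delay_ms(cfg), 40)
  expect_identical(total_delay_ms(delay_budget()), 64)
})

test_that("processing is causal: future samples do not affect the present", {
  x <- withr::with_seed(31, rnorm(4000))
  cfg <- preproc_config(fs_raw = 250, fs_proc = 250)
  a <- preprocess_chunks(pipeline_init(cfg), x)
  y <- x; y[3001:4000] <- y[3001:4000] + 100
  b <- preprocess_chunks(pipeline_init(cfg), y)
  expect_identical(a$clean[1:3000], b$clean[1:3000])
  expect_identical(a$envelope[1:3000], b$envelope[1:3000])
})
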
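# Stimulation policy, event-level scoring, threshold sweep, delay stats.

test_that("no stimulus is emitted while the output stays below threshold", {
  times <- seq(0, 10, by = 0.02)
  out <- rep(0.3, length(times))
  expect_identical(nrow(run_policy(out, times, stim_config(0.5))), 0L)
  # threshold 1.0 is unreachable for outputs in [0, 1]
  expect_identical(nrow(run_policy(rep(1, length(times)), times,
                                   stim_config(threshold = 1.0))), 0L)
})

test_that("a clean crossing stimulates once, 64 ms after the trigger", {
  times <- seq(0, 20, by = 0.02)
  out <- as.numeric(times >= 10 & times < 11)
  stim <- run_policy(out, times, stim_config(0.5))
  expect_identical(nrow(stim), 1L)
  expect_equal(stim$trigger_time_s, 10.0)
  expect_equal(stim$time_s, 10.064)
})

test_that("re-crossings within the refractory period are absorbed", {
  times <- seq(0, 20, by = 0.02)
  out <- numeric(length(times))
  out[times >= 4.0 & times < 5.0] <- 0.9    # episode 1 ends at 5.0
  out[times >= 5.2 & times < 5.6] <- 0.9    # re-crossing 0.2 s later
  stim <- run_policy(out, times, stim_config(0.5))
  expect_identical(nrow(stim), 1L)          # second episode absorbed
  expect_equal(stim$trigger_time_s, 4.0)
  # the absorbed episode restarts the timer at its own end (5.6):
  # an episode at 5.8 (0.2 s later) is still absorbed...
  out2 <- out; out2[times >= 5.8 & times < 6.0] <- 0.9
  expect_identical(nrow(run_policy(out2, times, stim_config(0.5))), 1L)
  # ...but an episode clearly past the refractory window fires again
  out3 <- out; out3[times >= 6.1 & times < 6.4] <- 0.9
  stim3 <- run_policy(out3, times, stim_config(0.5))
  expect_identical(nrow(stim3), 2L)
  expect_equal(stim3$trigger_time_s[2], 6.1)
})

test_that("non-monotone time vectors are rejected", {
  expect_error(run_policy(c(0.1, 0.9), c(1, 0.5), stim_config()), "increasing")
})

test_that("event scoring implements the interval TP/FP/FN definitions", {
  ev <- spindle_events(2.0, 1.0, 0.8)
  r1 <- score_stimulation(data.frame(time_s = 2.4), ev)
  expect_identical(c(r1$tp, r1$fp, r1$fn), c(1L, 0L, 0L))
  expect_equal(r1$delays_s, 0.4)

  # early stimulus: counted as FP, delay to the *closest* stimulus
  r2 <- score_stimulation(data.frame(time_s = c(1.9, 2.4)), ev)
  expect_identical(c(r2$tp, r2$fp, r2$fn), c(1L, 1L, 0L))
  expect_equal(r2$delays_s, -0.1)

  ev3 <- spindle_events(c(1, 5), c(1, 1), c(0.8, 0.8))
  r3 <- score_stimulation(data.frame(time_s = c(1.2, 1.8, 7.0)), ev3)
  expect_identical(c(r3$tp, r3$fp, r3$fn), c(1L, 2L, 1L))
  expect_equal(r3$precision, 1 / 3)
  expect_equal(r3$recall, 1 / 2)
  expect_equal(r3$f1, 0.4)

  expect_error(
    score_stimulation(data.frame(time_s = 1),
                      spindle_events(c(0, 0.5), c(1, 1), c(0.5, 0.5))),
    "overlap"
  )
})

test_that("every stimulus is TP or FP and tp + fn equals the event count", {
  for (seed in 1:25) {
    ev <- random_events(n_ev = 12, total_s = 120, seed = seed)
    st <- withr::with_seed(seed + 1000,
                           data.frame(time_s = sort(runif(20, 0, 120))))
    r <- score_stimulation(st, ev)
    expect_identical(r$tp + r$fp, nrow(st))
    expect_identical(r$tp + r$fn, nrow(ev))
    o <- oracle_event_score(st$time_s, ev$onset_s,
                            ev$onset_s + ev$duration_s)
    expect_identical(c(r$tp, r$fp, r$fn), c(o$tp, o$fp, o$fn))
  }
})

test_that("threshold sweep matches a brute-force re-scoring scan", {
  times <- seq(0, 60, by = 0.02)
  out <- withr::with_seed(3, {
    raw <- stats::filter(runif(length(times)), rep(1 / 25, 25), sides = 1)
    as.numeric(ifelse(is.na(raw), 0, raw))
  })
  ev <- random_events(n_ev = 5, total_s = 60, seed = 4)
  ths <- seq(0.3, 0.7, by = 0.1)
  sw <- threshold_sweep(out, times, ev, ths)
  brute <- vapply(ths, function(th) {
    score_stimulation(run_policy(out, times, stim_config(th)), ev)$f1
  }, numeric(1))
  expect_equal(sw$curve$f1, brute)
  expect_equal(sw$best_threshold, ths[which.max(brute)])
})

test_that("stimulus count never increases with threshold on unimodal episodes", {
  # smooth, single-peak episodes: raising the threshold can only shrink or
  # drop episodes, never split them
  times <- seq(0, 120, by = 0.02)
  out <- numeric(length(times))
  peaks <- seq(5, 115, by = 6)
  for (p in peaks) {
    out <- pmax(out, withr::with_seed(as.integer(p), runif(1)) *
                       exp(-(times - p)^2 / 0.5))
  }
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(th) {
    nrow(run_policy(out, times, stim_config(th)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("delay statistics use the population formula and flag empties", {
  r <- list(delays_s = rep(0.1, 5))
  ds <- delay_stats(r)
  expect_equal(ds$mean_s, 0.1)
  expect_equal(ds$sd_s, 0)
  ds2 <- delay_stats(list(delays_s = c(-0.1, 0.3)))
  expect_equal(ds2$mean_s, 0.1)
  expect_equal(ds2$sd_s, 0.2)
  ds0 <- delay_stats(list(delays_s = numeric()))
  expect_true(ds0$empty)
  expect_identical(ds0$n, 0L)
  expect_false(any(is.nan(unlist(ds0[c("mean_s", "sd_s")]))))
})

test_that("policy output is invariant to how the series was produced", {
  # same output series assembled from chunked vs whole preprocessing
  x <- withr::with_seed(6, rnorm(10000, sd = 15))
  cfg <- preproc_config()
  whole <- preprocess_chunks(pipeline_init(cfg), x)
  ch <- chunked_preprocess(x, cfg, rep(777, 20))
  times <- seq_along(whole$envelope) / 250
  s1 <- run_policy(bandpower_baseline(whole$envelope), times, stim_config())
  s2 <- run_policy(bandpower_baseline(ch$envelope), times, stim_config())
  expect_identical(s1, s2)
})
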
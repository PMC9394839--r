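# Pareto bookkeeping, surrogate, acquisition and the search loop.

pp <- function(hw, sw, a = list(x = hw)) pareto_point(a, hw, sw)

test_that("domination follows the strict/weak definition", {
  expect_true(dominates(pp(100, 0.3), pp(200, 0.4)))
  expect_false(dominates(pp(100, 0.4), pp(200, 0.3)))
  expect_false(dominates(pp(200, 0.3), pp(100, 0.4)))
  a <- pp(100, 0.3)
  expect_false(dominates(a, a))
  # equal on one axis, better on the other
  expect_true(dominates(pp(100, 0.3), pp(100, 0.4)))
})

test_that("streaming front updates equal brute-force filtering", {
  expect_length(update_front(list(), pp(10, 0.5)), 1)
  front <- update_front(update_front(list(), pp(100, 0.2)), pp(50, 0.5))
  # a dominated point (beaten by (100, 0.2)) leaves the front unchanged
  expect_identical(update_front(front, pp(120, 0.3)), front)
  for (seed in 1:5) {
    pts <- withr::with_seed(seed, lapply(1:100, function(i) {
      pp(sample(1:5000, 1), runif(1))
    }))
    front <- list()
    for (p in pts) front <- update_front(front, p)
    brute <- pareto_filter(pts)
    expect_equal(
      lapply(front, function(p) c(p$hw_cost, p$sw_cost)),
      lapply(brute, function(p) c(p$hw_cost, p$sw_cost))
    )
  }
})

test_that("the surrogate recovers a planted linear cost surface", {
  space <- search_space(list(gru_hidden = c(8, 16, 32, 64),
                             dilation_k = c(1, 2, 4, 8)))
  asn <- spindleloop:::enumerate_space(space)
  truth <- function(a) {
    e <- spindleloop:::encode_assignment(a, space)
    0.1 + 0.5 * e[1] + 0.2 * e[2]
  }
  hist <- lapply(asn[1:12], function(a) pareto_point(a, 1, truth(a)))
  sur <- fit_surrogate(hist, space)
  held_out <- asn[13:16]
  errs <- vapply(held_out, function(a) {
    abs(predict_surrogate(sur, a) - truth(a))
  }, numeric(1))
  expect_lt(max(errs), 1e-10)
})

test_that("degenerate histories fall back to constants", {
  space <- search_space(list(gru_hidden = c(8, 16)))
  expect_equal(predict_surrogate(fit_surrogate(list(), space),
                                 list(gru_hidden = 8)), 0.5)
  one <- list(pareto_point(list(gru_hidden = 16), 10, 0.31))
  expect_equal(predict_surrogate(fit_surrogate(one, space),
                                 list(gru_hidden = 8)), 0.31)
})

test_that("pure exploration proposes uniformly over the space", {
  space <- search_space(list(gru_hidden = c(8, 16, 32)))
  draws <- vapply(1:6000, function(i) {
    propose(NULL, space, explore_eps = 1, seed = i)$gru_hidden
  }, numeric(1))
  counts <- table(draws)
  expect_identical(length(counts), 3L)
  chisq <- sum((counts - 2000)^2 / 2000)
  expect_lt(chisq, qchisq(0.999, df = 2))
  # fixed seed -> identical proposal
  expect_identical(propose(NULL, space, 1, seed = 7),
                   propose(NULL, space, 1, seed = 7))
})

test_that("greedy proposals with an exact surrogate pick the argmin", {
  space <- search_space(list(gru_hidden = c(8, 16, 32, 64),
                             dilation_k = c(1, 2, 4, 8)))
  asn <- spindleloop:::enumerate_space(space)
  truth <- function(a) {
    e <- spindleloop:::encode_assignment(a, space)
    0.1 + 0.5 * e[1] + 0.2 * e[2]
  }
  hist <- lapply(asn, function(a) pareto_point(a, 1, truth(a)))
  sur <- fit_surrogate(hist, space)
  best <- propose(sur, space, explore_eps = 0, seed = 3, m = 16)
  # global argmin: smallest hidden size and dilation
  expect_equal(best$gru_hidden, 8)
  expect_equal(best$dilation_k, 1)
})

# A deterministic mock trainer with an analytic cost surface: bigger
# recurrent width helps, with diminishing returns.
mock_trainer <- function(cfg, seed) {
  0.4 + 0.2 * log2(cfg$gru_hidden) / 6 + 0.05 * (cfg$dilation_k > 1)
}

toy_space <- function() {
  search_space(
    list(gru_hidden = c(8, 16, 32, 64), dilation_k = c(1, 2, 8)),
    build = function(a) {
      detector_config(window_samples = 32, conv_blocks = list(c(4, 7, 2)),
                      gru_hidden = a$gru_hidden, dilation_k = a$dilation_k)
    }
  )
}

test_that("an exhaustive search reproduces the brute-force front", {
  space <- toy_space()
  res <- run_search(space, budget = 12, trainer = mock_trainer, seed = 2)
  expect_length(res$history, 12)
  keys <- vapply(res$history, function(p) {
    spindleloop:::assignment_key(p$assignment)
  }, character(1))
  expect_identical(anyDuplicated(keys), 0L)
  brute <- pareto_filter(res$history)
  expect_equal(front_table(res$front), front_table(brute))
  # selected = right-hand end of the front (minimal software cost)
  sws <- vapply(res$front, `[[`, numeric(1), "sw_cost")
  expect_equal(res$selected$sw_cost, min(sws))
})

test_that("budget 1 yields a single evaluated point which is selected", {
  res <- run_search(toy_space(), budget = 1, trainer = mock_trainer, seed = 5)
  expect_length(res$history, 1)
  expect_length(res$front, 1)
  expect_identical(res$selected$assignment, res$history[[1]]$assignment)
})

test_that("the evaluated set is invariant to the worker count", {
  space <- toy_space()
  key_set <- function(res) {
    sort(vapply(res$history, function(p) {
      spindleloop:::assignment_key(p$assignment)
    }, character(1)))
  }
  r1 <- run_search(space, budget = 8, trainer = mock_trainer,
                   n_workers = 1, explore_eps = 1, seed = 11)
  r4 <- run_search(space, budget = 8, trainer = mock_trainer,
                   n_workers = 4, explore_eps = 1, seed = 11)
  expect_identical(key_set(r1), key_set(r4))
})

test_that("trainer failures are excluded and the search continues", {
  flaky <- function(cfg, seed) {
    if (cfg$gru_hidden == 16) stop("worker crash")
    mock_trainer(cfg, seed)
  }
  res <- run_search(toy_space(), budget = 12, trainer = flaky, seed = 4)
  expect_length(res$failed, 3)  # 16-hidden appears with 3 dilation values
  expect_length(res$history, 9)
  hid <- vapply(res$front, function(p) p$assignment$gru_hidden, numeric(1))
  expect_false(any(hid == 16))
  expect_false(is.null(res$selected))
})

test_that("hardware cost in search results equals the analytic count", {
  space <- toy_space()
  res <- run_search(space, budget = 3, trainer = mock_trainer, seed = 6)
  for (p in res$history) {
    expect_identical(p$hw_cost,
                     as.numeric(count_parameters(space$build(p$assignment))))
  }
})
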
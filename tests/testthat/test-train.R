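# Training, oversampling, metrics, and the subject-wise protocol.

test_that("make_examples follows the window/stride arithmetic", {
  cfg <- toy_detector_config()
  expect_length(make_examples(rnorm(10), NULL, integer(10), NULL, cfg)$ends, 0)
  n <- 500
  ex <- make_examples(rnorm(n), NULL, integer(n), NULL, cfg)
  expect_length(ex$ends, (n - 32) %/% 5 + 1)
  ex1 <- make_examples(rnorm(100), NULL, rep(1L, 100), NULL, cfg)
  expect_true(all(ex1$binary == 1L))
  # window ending at sample n carries the target of sample n
  some_end <- ex$ends[20]
  lab <- integer(n); lab[some_end] <- 1L
  ex2 <- make_examples(rnorm(n), NULL, lab, NULL, cfg)
  expect_identical(ex2$binary[ex2$ends == some_end], 1L)
  expect_identical(sum(ex2$binary), 1L)
})

test_that("oversampled batches are half positive in expectation", {
  b <- oversampled_batches(pos_idx = 1:50, neg_idx = 51:1000,
                           batch_size = 100, n_batches = 100, seed = 3)
  frac <- mean(unlist(b) <= 50)
  expect_lt(abs(frac - 0.5), 0.02)
  # already balanced pools stay balanced
  b2 <- oversampled_batches(1:500, 501:1000, 100, 100, seed = 4)
  expect_lt(abs(mean(unlist(b2) <= 500) - 0.5), 0.02)
  expect_error(oversampled_batches(integer(), 1:10, 10, 1), "no positive")
})

test_that("zero training steps leave the model unchanged", {
  cfg <- toy_detector_config()
  toy <- separable_toy(n_seg = 4)
  ex <- make_examples(toy$x, NULL, toy$labels, NULL, cfg)
  mod <- build_detector(cfg, seed = 1)
  tr <- train_detector(mod, ex, train_config(steps = 0))
  expect_identical(tr$model$params, mod$params)
  expect_length(tr$loss_curve, 0)
})

test_that("training solves a separable burst-vs-noise problem", {
  cfg <- toy_detector_config()
  toy <- separable_toy()
  ex <- make_examples(toy$x, NULL, toy$labels, NULL, cfg)
  tc <- train_config(steps = 400, batch_size = 32, seed = 2)
  tr <- train_detector(build_detector(cfg, seed = 1), ex, tc)
  # smoothed loss decreases
  expect_lt(mean(tail(tr$loss_curve, 50)), 0.5 * mean(head(tr$loss_curve, 50)))
  f1 <- sample_metrics(predict_examples(tr$model, ex), ex$binary)$f1
  expect_gt(f1, 0.95)
  # deterministic for fixed seeds and batch order
  tr2 <- train_detector(build_detector(cfg, seed = 1), ex, tc)
  expect_identical(tr$model$params, tr2$model$params)
})

test_that("a regressor trained on a constant target predicts it", {
  cfg <- toy_detector_config(output_head = "regressor")
  toy <- separable_toy(n_seg = 20)
  ex <- make_examples(toy$x, NULL, toy$labels,
                      rep(0.3, length(toy$x)), cfg)
  tr <- train_detector(build_detector(cfg, seed = 1), ex,
                       train_config(steps = 300, batch_size = 32, seed = 2))
  pred <- predict_examples(tr$model, ex)
  expect_lt(abs(mean(pred) - 0.3), 0.05)
})

test_that("sample metrics implement the stated formulas and conventions", {
  m <- sample_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_identical(c(m$precision, m$recall, m$f1), c(1, 1, 1))
  # TP = 2, FP = 1, FN = 2
  m2 <- sample_metrics(c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1),
                       c(1, 1, 0, 1, 1, 0))
  expect_equal(m2$precision, 2 / 3)
  expect_equal(m2$recall, 1 / 2)
  expect_equal(m2$f1, 4 / 7)
  # all-negative predictions: zero-division convention
  m3 <- sample_metrics(rep(0, 4), c(1, 0, 1, 0))
  expect_identical(c(m3$precision, m3$recall, m3$f1), c(0, 0, 0))
})

test_that("best_threshold matches a brute-force scan and breaks ties low", {
  labs <- withr::with_seed(4, as.integer(runif(500) < 0.3))
  outs <- withr::with_seed(5, pmin(pmax(labs * 0.6 + rnorm(500, 0, 0.25), 0), 1))
  grid <- seq(0.05, 0.95, by = 0.05)
  bt <- best_threshold(outs, labs, grid)
  brute <- vapply(grid, function(th) sample_metrics(outs, labs, th)$f1,
                  numeric(1))
  expect_equal(bt$f1, max(brute))
  expect_equal(bt$threshold, grid[which.max(brute)])
  # outputs equal to labels: every threshold perfect, lowest returned
  perfect <- best_threshold(c(0, 1, 1, 0), c(0, 1, 1, 0), grid)
  expect_equal(perfect$threshold, grid[1])
  expect_equal(perfect$f1, 1)
})

test_that("subject splits honor the fractions with floor rounding, min 1", {
  subs100 <- sprintf("S%03d", 1:100)
  sp <- subject_splits(subs100, split_plan(n_shuffles = 3, seed = 9))
  for (s in sp) {
    expect_length(s$val, 10)
    expect_length(s$test, 10)
    expect_length(s$train, 80)
    expect_length(intersect(s$val, s$test), 0)
    expect_length(intersect(s$val, s$train), 0)
    expect_length(intersect(s$test, s$train), 0)
    expect_setequal(c(s$val, s$test, s$train), subs100)
  }
  sp10 <- subject_splits(sprintf("S%02d", 1:10), split_plan(n_shuffles = 1))
  expect_length(sp10[[1]]$val, 1)
  expect_length(sp10[[1]]$test, 1)
  expect_length(sp10[[1]]$train, 8)
  expect_identical(subject_splits(subs100, split_plan(seed = 2)),
                   subject_splits(subs100, split_plan(seed = 2)))
})

make_subject_data <- function(n_subjects, cfg, seed = 1) {
  out <- list()
  for (i in seq_len(n_subjects)) {
    toy <- separable_toy(n_seg = 8, seed = seed + i)
    out[[sprintf("S%02d", i)]] <- list(
      phase = if (i %% 2 == 0) "older" else "younger",
      examples = make_examples(toy$x, NULL, toy$labels, NULL, cfg)
    )
  }
  out
}

test_that("the selection protocol picks the best validation model", {
  cfg <- toy_detector_config()
  sdata <- make_subject_data(6, cfg)
  plan <- split_plan(n_shuffles = 2, val_frac = 0.2, test_frac = 0.2,
                     models_per_split = 3, seed = 5)
  # sabotage: the third model of each split stays untrained (random weights)
  counter <- new.env(); counter$n <- 0L
  train_fun <- function(dcfg, ex, seed) {
    counter$n <- counter$n + 1L
    m <- build_detector(dcfg, seed = seed)
    if (counter$n %% 3L == 0L) return(m)
    train_detector(m, ex, train_config(steps = 150, batch_size = 32,
                                       seed = seed))$model
  }
  rep1 <- selection_protocol(sdata, plan, cfg, train_fun = train_fun)
  expect_s3_class(rep1, "metrics_report")
  whole_f1 <- rep1$mean[rep1$group == "whole" & rep1$metric == "f1"]
  expect_gt(whole_f1, 0.8)  # a sabotaged model would score near chance
  # same master seed -> identical report
  rep2 <- selection_protocol(sdata, plan, cfg, train_fun = train_fun)
  expect_identical(rep1, rep2)
})

test_that("a degenerate plan reduces to a single train/val/test run", {
  cfg <- toy_detector_config()
  sdata <- make_subject_data(5, cfg)
  plan <- split_plan(n_shuffles = 1, val_frac = 0.2, test_frac = 0.2,
                     models_per_split = 1, seed = 3)
  mock_train <- function(dcfg, ex, seed) build_detector(dcfg, seed = 1)
  rep1 <- selection_protocol(sdata, plan, cfg, train_fun = mock_train)
  expect_identical(nrow(rep1), 9L)  # 3 groups x 3 metrics
  expect_true(all(is.na(rep1$sd) | rep1$sd == 0))
})
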
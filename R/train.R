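# Supervised training on windowed examples, subject-wise evaluation
# protocol, and sample-level metrics.
#
# Classifiers are trained on binary labels with binary cross-entropy and
# benefit from 50/50 oversampling of the rare positive class; regressors are
# trained on the raw consensus scores with mean squared error and no
# rebalancing. Training unrolls the recurrent unit over short sequences of
# windows spaced `dilation_k * stride` samples apart -- exactly the substream
# one virtual network sees -- with the loss on the final step.

#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Sequences per gradient step (default 64).
#' @param steps Number of gradient updates (default 400). `steps = 0` leaves
#'   the model untouched.
#' @param seq_len Windows per training sequence (default 8); the recurrent
#'   state is unrolled over these, loss on the last window.
#' @param burn_in Pre-sequence windows run without gradients to warm the
#'   recurrent state into its mid-stream regime before the loss window
#'   (default 8). Zero disables warm-up.
#' @param oversample `TRUE` to draw 50% positive / 50% negative sequences per
#'   batch. Default `NULL`: on for classifiers, off for regressors.
#' @param seed RNG seed for batch sampling and dropout.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(lr = 1e-3, batch_size = 64, steps = 400,
                         seq_len = 8, burn_in = 8, oversample = NULL,
                         seed = 1) {
  stopifnot(lr > 0, batch_size >= 1, steps >= 0, seq_len >= 1, burn_in >= 0)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 steps = as.integer(steps), seq_len = as.integer(seq_len),
                 burn_in = as.integer(burn_in),
                 oversample = oversample, seed = seed),
            class = "train_config")
}

#' Build windowed examples from preprocessed signals
#'
#' The window ending at sample `n` is paired with the target of sample `n`;
#' windows are generated every `stride_samples`. A signal shorter than one
#' window yields an empty example set.
#'
#' @param clean Cleaned-branch series at the processing rate.
#' @param envelope Envelope-branch series (used for 2-input models; may be
#'   `NULL` for single-input configs).
#' @param binary Per-sample binary labels aligned with `clean`.
#' @param score Per-sample consensus scores aligned with `clean` (optional;
#'   defaults to `binary`).
#' @param config A [detector_config()].
#' @return An object of class `"example_set"`: signal matrix, window end
#'   indices, and per-window binary/score targets.
#' @export
make_examples <- function(clean, envelope = NULL, binary, score = NULL,
                          config = detector_config()) {
  n <- length(clean)
  stopifnot(length(binary) == n)
  score <- score %||% as.numeric(binary)
  C <- n_input_channels(config)
  sig <- if (C == 2L) {
    stopifnot(!is.null(envelope), length(envelope) == n)
    cbind(clean, envelope)
  } else matrix(clean, ncol = 1L)
  w <- config$window_samples
  ends <- if (n < w) integer() else seq(w, n, by = config$stride_samples)
  structure(list(
    signals = sig, ends = as.integer(ends),
    binary = as.integer(binary)[ends], score = as.numeric(score)[ends],
    window = w, stride = config$stride_samples,
    dilation_k = config$dilation_k, channels = C
  ), class = "example_set")
}

#' @export
print.example_set <- function(x, ...) {
  cat(sprintf("<example_set> %d windows (%d samples, %d channel%s), %.1f%% positive\n",
              length(x$ends), x$window, x$channels,
              if (x$channels > 1) "s" else "",
              100 * mean(x$binary)))
  invisible(x)
}

# Window ends usable as the *last* element of a training sequence of length
# seq_len with per-step spacing d = dilation_k * stride.
valid_sequence_ends <- function(ex, seq_len) {
  d <- ex$dilation_k * ex$stride
  need <- ex$window + (seq_len - 1L) * d
  which(ex$ends >= need)
}

# Warm up the recurrent state over `burn_in` pre-sequence windows without
# caching gradients, so the states entering the loss window resemble the
# steady mid-stream states seen at inference time (plain truncated BPTT
# with a zero initial state trains against an atypical state distribution).
sequence_burn_in <- function(model, ex, batch, burn_in, len) {
  cfg <- model$config
  L <- cfg$gru_layers
  B <- length(batch)
  H <- cfg$gru_hidden
  hidden <- replicate(L, matrix(0, B, H), simplify = FALSE)
  total <- burn_in + len
  for (t in seq_len(burn_in)) {
    X <- sequence_step_array(ex, batch, t, total)
    x <- conv_stack_forward(X, model$params$conv, conv_pools(cfg))$feat
    for (l in seq_len(L)) {
      g <- gru_forward(x, hidden[[l]], model$params$gru[[l]])
      hidden[[l]] <- g$h
      x <- g$h
    }
  }
  hidden
}

# Assemble the (B, W, C) window array for the t-th step of sequences ending
# at `end_idx` (indices into ex$ends).
sequence_step_array <- function(ex, end_idx, t, seq_len) {
  d <- ex$dilation_k * ex$stride
  ends <- ex$ends[end_idx] - (seq_len - t) * d
  B <- length(ends)
  X <- array(0, c(B, ex$window, ex$channels))
  for (b in seq_len(B)) {
    X[b, , ] <- ex$signals[(ends[b] - ex$window + 1L):ends[b], ]
  }
  X
}

#' Class-balancing batch sampler
#'
#' Draws index batches whose expected positive fraction is 0.5: each slot is
#' positive with probability 1/2, drawn with replacement from the positive
#' pool (and likewise for negatives).
#'
#' @param pos_idx,neg_idx Index pools for the two classes.
#' @param batch_size Batch size.
#' @param n_batches Number of batches to draw.
#' @param seed RNG seed.
#' @return List of `n_batches` integer vectors.
#' @export
oversampled_batches <- function(pos_idx, neg_idx, batch_size, n_batches,
                                seed = 1) {
  if (!length(pos_idx)) {
    stop("cannot balance batches: no positive examples", call. = FALSE)
  }
  if (!length(neg_idx)) {
    stop("cannot balance batches: no negative examples", call. = FALSE)
  }
  with_seed(seed, lapply(seq_len(n_batches), function(i) {
    take_pos <- runif(batch_size) < 0.5
    out <- integer(batch_size)
    out[take_pos] <- pos_idx[sample.int(length(pos_idx), sum(take_pos),
                                        replace = TRUE)]
    out[!take_pos] <- neg_idx[sample.int(length(neg_idx), sum(!take_pos),
                                         replace = TRUE)]
    out
  }))
}

uniform_batches <- function(idx, batch_size, n_batches, seed = 1) {
  with_seed(seed, lapply(seq_len(n_batches), function(i) {
    idx[sample.int(length(idx), batch_size, replace = TRUE)]
  }))
}

# Forward + backward over one sequence batch; returns loss and gradients.
sequence_grad <- function(model, ex, batch, len, target, drop_mask,
                          burn_in = 0L) {
  cfg <- model$config
  params <- model$params
  L <- cfg$gru_layers
  B <- length(batch)
  H <- cfg$gru_hidden
  pools <- conv_pools(cfg)

  conv_caches <- vector("list", len)
  gru_caches <- vector("list", len)
  hidden <- if (burn_in > 0L) {
    sequence_burn_in(model, ex, batch, burn_in, len)
  } else {
    replicate(L, matrix(0, B, H), simplify = FALSE)
  }
  total <- burn_in + len
  x_top <- NULL
  for (t in seq_len(len)) {
    X <- sequence_step_array(ex, batch, burn_in + t, total)
    cs <- conv_stack_forward(X, params$conv, pools)
    conv_caches[[t]] <- cs
    x <- cs$feat
    gc <- vector("list", L)
    for (l in seq_len(L)) {
      g <- gru_forward(x, hidden[[l]], params$gru[[l]])
      hidden[[l]] <- g$h
      gc[[l]] <- g$cache
      x <- g$h
    }
    gru_caches[[t]] <- gc
    x_top <- x
  }
  h_head <- if (is.null(drop_mask)) x_top else x_top * drop_mask
  fwd <- head_forward(h_head, params$head, cfg$output_head)
  lg <- head_loss_grad(fwd, target, cfg$output_head)
  hb <- head_backward(lg$dlin, h_head, params$head)

  grads <- zeros_like_params(params)
  grads$head$W <- hb$dW
  grads$head$b <- hb$db
  dhid <- replicate(L, matrix(0, B, H), simplify = FALSE)
  dhid[[L]] <- if (is.null(drop_mask)) hb$dh else hb$dh * drop_mask
  for (t in rev(seq_len(len))) {
    carry <- NULL
    for (l in rev(seq_len(L))) {
      dh_new <- dhid[[l]]
      if (!is.null(carry)) dh_new <- dh_new + carry
      gb <- gru_backward(dh_new, params$gru[[l]], gru_caches[[t]][[l]])
      grads$gru[[l]]$W_ih <- grads$gru[[l]]$W_ih + gb$dW_ih
      grads$gru[[l]]$W_hh <- grads$gru[[l]]$W_hh + gb$dW_hh
      grads$gru[[l]]$b_ih <- grads$gru[[l]]$b_ih + gb$db_ih
      grads$gru[[l]]$b_hh <- grads$gru[[l]]$b_hh + gb$db_hh
      dhid[[l]] <- gb$dh
      carry <- gb$dx
    }
    cb <- conv_stack_backward(carry, params$conv, conv_caches[[t]])
    for (i in seq_along(params$conv)) {
      grads$conv[[i]]$W <- grads$conv[[i]]$W + cb$grads[[i]]$dW
      grads$conv[[i]]$b <- grads$conv[[i]]$b + cb$grads[[i]]$db
    }
  }
  list(loss = lg$loss, grads = grads)
}

#' Train a detector
#'
#' Runs `config$steps` Adam updates on sequence batches drawn from
#' `examples`. Classifiers use binary cross-entropy on the binary targets
#' (with 50/50 oversampling by default); regressors use mean squared error
#' on the score targets (no rebalancing by default). Deterministic for a
#' fixed seed and batch order. A non-finite loss aborts with diagnostics.
#'
#' @param model A [build_detector()] model.
#' @param examples An [make_examples()] example set.
#' @param config A [train_config()].
#' @return `list(model, loss_curve)`.
#' @export
train_detector <- function(model, examples, config = train_config()) {
  stopifnot(inherits(model, "spindle_detector"),
            inherits(examples, "example_set"))
  cfg <- model$config
  if (config$steps == 0L) {
    return(list(model = model, loss_curve = numeric()))
  }
  is_clf <- cfg$output_head == "classifier"
  oversample <- config$oversample %||% is_clf
  usable <- valid_sequence_ends(examples, config$seq_len + config$burn_in)
  if (!length(usable)) {
    stop("no window sequences fit in the examples; signal too short",
         call. = FALSE)
  }
  batches <- if (oversample) {
    oversampled_batches(usable[examples$binary[usable] == 1L],
                        usable[examples$binary[usable] == 0L],
                        config$batch_size, config$steps,
                        seed = derive_seed(config$seed, "batches"))
  } else {
    uniform_batches(usable, config$batch_size, config$steps,
                    seed = derive_seed(config$seed, "batches"))
  }
  opt <- adam_init(model$params, lr = config$lr)
  loss_curve <- numeric(config$steps)
  drop_seed <- derive_seed(config$seed, "dropout")
  for (s in seq_len(config$steps)) {
    batch <- batches[[s]]
    target <- if (is_clf) examples$binary[batch] else examples$score[batch]
    drop_mask <- NULL
    if (cfg$dropout > 0) {
      drop_mask <- with_seed(drop_seed + s, {
        matrix(runif(length(batch) * cfg$gru_hidden) >= cfg$dropout,
               length(batch), cfg$gru_hidden) / (1 - cfg$dropout)
      })
    }
    sg <- sequence_grad(model, examples, batch, config$seq_len, target,
                        drop_mask, burn_in = config$burn_in)
    if (!is.finite(sg$loss)) {
      stop(sprintf("training aborted: non-finite loss at step %d (lr %.3g)",
                   s, config$lr), call. = FALSE)
    }
    loss_curve[s] <- sg$loss
    st <- adam_step(opt, model$params, sg$grads)
    opt <- st$opt
    model$params <- st$params
  }
  list(model = model, loss_curve = loss_curve)
}

#' Replay a detector over an example set
#'
#' Produces the per-window output series (equivalent to streaming
#' [forward_step()] calls from a fresh state).
#'
#' @param model A [build_detector()] model.
#' @param examples An [make_examples()] example set.
#' @return Numeric outputs, one per window.
#' @export
predict_examples <- function(model, examples) {
  N <- length(examples$ends)
  if (!N) return(numeric())
  W <- examples$window
  X <- array(0, c(N, W, examples$channels))
  for (i in seq_len(N)) {
    X[i, , ] <- examples$signals[(examples$ends[i] - W + 1L):examples$ends[i], ]
  }
  detect_series(model, X)
}

# ---- metrics ----------------------------------------------------------------

#' Sample-level precision, recall and f1
#'
#' Computed per data point. Zero-division convention: precision is 0 when no
#' positives are predicted, recall is 0 when there are no positive labels,
#' and f1 is 0 when precision + recall is 0.
#'
#' @param predictions Numeric outputs in `[0, 1]`.
#' @param labels Binary labels.
#' @param threshold Prediction cutoff (default 0.5).
#' @return `list(precision, recall, f1, tp, fp, fn, tn)`.
#' @export
sample_metrics <- function(predictions, labels, threshold = 0.5) {
  stopifnot(length(predictions) == length(labels))
  pred <- predictions >= threshold
  lab <- labels == 1L
  tp <- sum(pred & lab); fp <- sum(pred & !lab)
  fn <- sum(!pred & lab); tn <- sum(!pred & !lab)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Best detection threshold on binary labels
#'
#' Exhaustive grid argmax of the sample-level f1; ties break toward the
#' lower threshold.
#'
#' @param outputs Detector (typically regressor) outputs.
#' @param labels Binary labels.
#' @param grid Candidate thresholds (default 0.01 to 0.99 by 0.01).
#' @return `list(threshold, f1)`.
#' @export
best_threshold <- function(outputs, labels, grid = seq(0.01, 0.99, by = 0.01)) {
  f1s <- vapply(grid, function(th) {
    sample_metrics(outputs, labels, th)$f1
  }, numeric(1))
  i <- which.max(f1s)
  list(threshold = grid[i], f1 = f1s[i])
}

# ---- subject-wise protocol --------------------------------------------------

#' Subject split plan
#'
#' @param n_shuffles Number of independent subject shuffles (default 10).
#' @param val_frac,test_frac Fractions of subjects held out for validation
#'   and test (default 0.10 each; rounding is `floor`, minimum 1 subject).
#' @param models_per_split Models trained per split, differing only by seed
#'   (default 3).
#' @param seed Master seed for the shuffles.
#' @return An object of class `"split_plan"`.
#' @export
split_plan <- function(n_shuffles = 10, val_frac = 0.10, test_frac = 0.10,
                       models_per_split = 3, seed = 1) {
  stopifnot(n_shuffles >= 1, val_frac > 0, test_frac > 0,
            val_frac + test_frac < 1, models_per_split >= 1)
  structure(list(n_shuffles = as.integer(n_shuffles), val_frac = val_frac,
                 test_frac = test_frac,
                 models_per_split = as.integer(models_per_split),
                 seed = seed),
            class = "split_plan")
}

#' Subject-wise train/validation/test splits
#'
#' Each shuffle partitions the subjects: `floor(val_frac * n)` (min 1) into
#' validation, `floor(test_frac * n)` (min 1) into test, the rest into
#' training. No subject appears in two sets of the same shuffle.
#'
#' @param subjects Character vector of subject identifiers.
#' @param plan A [split_plan()].
#' @return List of `n_shuffles` lists with `train`, `val`, `test`.
#' @export
subject_splits <- function(subjects, plan = split_plan()) {
  n <- length(subjects)
  n_val <- max(1L, floor(plan$val_frac * n))
  n_test <- max(1L, floor(plan$test_frac * n))
  if (n_val + n_test >= n) stop("too few subjects to split", call. = FALSE)
  lapply(seq_len(plan$n_shuffles), function(s) {
    perm <- with_seed(derive_seed(plan$seed, s), sample(subjects))
    list(val = perm[seq_len(n_val)],
         test = perm[n_val + seq_len(n_test)],
         train = perm[(n_val + n_test + 1L):n])
  })
}

# Concatenate examples of several subjects into one training set.
combine_examples <- function(ex_list) {
  base <- ex_list[[1]]
  offs <- 0L
  ends <- integer(); binary <- integer(); score <- numeric()
  sigs <- vector("list", length(ex_list))
  for (i in seq_along(ex_list)) {
    ex <- ex_list[[i]]
    sigs[[i]] <- ex$signals
    ends <- c(ends, ex$ends + offs)
    binary <- c(binary, ex$binary)
    score <- c(score, ex$score)
    offs <- offs + nrow(ex$signals)
  }
  structure(list(signals = do.call(rbind, sigs), ends = ends,
                 binary = binary, score = score, window = base$window,
                 stride = base$stride, dilation_k = base$dilation_k,
                 channels = base$channels),
            class = "example_set")
}

# NOTE: combining subjects concatenates their signals; the few windows
# straddling a subject boundary are a negligible fraction at these stride
# settings and are tolerated for training only (evaluation is per subject).

#' Subject-wise model selection and evaluation protocol
#'
#' For each shuffle of the plan: train `models_per_split` models (identical
#' config, different seeds) on the training subjects, select the one with the
#' best sample-level validation f1, and evaluate it on the test subjects.
#' Metrics are reported per phase (younger / older cohorts) and for the whole
#' cohort, as mean and sd over shuffles.
#'
#' @param subject_data Named list: per subject, a list with `phase`
#'   (`"younger"` or `"older"`) and an `examples` [make_examples()] set.
#' @param plan A [split_plan()].
#' @param det_config A [detector_config()].
#' @param tr_config A [train_config()].
#' @param threshold Prediction cutoff for classifier metrics (default 0.5).
#' @param train_fun Training backend, by default [train_detector()] on a
#'   freshly built model; replaceable for testing the protocol itself.
#' @return A data frame (class `"metrics_report"`): one row per
#'   (group, metric) with mean and sd over shuffles.
#' @export
selection_protocol <- function(subject_data, plan = split_plan(),
                               det_config = detector_config(),
                               tr_config = train_config(),
                               threshold = 0.5, train_fun = NULL) {
  train_fun <- train_fun %||% function(cfg, ex, seed) {
    tc <- tr_config; tc$seed <- seed
    train_detector(build_detector(cfg, seed = seed), ex, tc)$model
  }
  splits <- subject_splits(names(subject_data), plan)
  eval_set <- function(model, subjects) {
    if (!length(subjects)) return(NULL)
    preds <- unlist(lapply(subjects, function(s) {
      predict_examples(model, subject_data[[s]]$examples)
    }))
    labs <- unlist(lapply(subjects, function(s) {
      subject_data[[s]]$examples$binary
    }))
    sample_metrics(preds, labs, threshold)
  }
  groups <- c("phase1", "phase2", "whole")
  acc <- array(NA_real_, c(plan$n_shuffles, 3L, 3L),
               dimnames = list(NULL, groups, c("recall", "precision", "f1")))
  for (s in seq_along(splits)) {
    sp <- splits[[s]]
    train_ex <- combine_examples(lapply(sp$train, function(x) {
      subject_data[[x]]$examples
    }))
    models <- lapply(seq_len(plan$models_per_split), function(m) {
      train_fun(det_config, train_ex, derive_seed(plan$seed, s * 100 + m))
    })
    val_f1 <- vapply(models, function(mod) eval_set(mod, sp$val)$f1, numeric(1))
    best <- models[[which.max(val_f1)]]
    phase_of <- vapply(sp$test, function(x) subject_data[[x]]$phase, character(1))
    sets <- list(phase1 = sp$test[phase_of == "younger"],
                 phase2 = sp$test[phase_of == "older"],
                 whole = sp$test)
    for (g in seq_along(sets)) {
      m <- eval_set(best, sets[[g]])
      if (!is.null(m)) {
        acc[s, g, ] <- c(m$recall, m$precision, m$f1)
      }
    }
  }
  out <- expand.grid(group = groups, metric = c("recall", "precision", "f1"),
                     stringsAsFactors = FALSE)
  out$mean <- mapply(function(g, met) mean(acc[, g, met], na.rm = TRUE),
                     out$group, out$metric)
  out$sd <- mapply(function(g, met) sd(acc[, g, met], na.rm = TRUE),
                   out$group, out$metric)
  class(out) <- c("metrics_report", "data.frame")
  out
}
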
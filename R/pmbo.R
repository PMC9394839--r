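# Pareto-front design-space exploration.
#
# Each candidate detector configuration has two costs: a hardware cost (the
# exact trainable-parameter count, free to compute) and a software cost
# (1 - f1 of the fully trained model, expensive to evaluate). The search
# maintains the set of non-dominated configurations, guides proposals with a
# cheap regression surrogate over encoded configurations, and finally selects
# the front member with the lowest software cost (the right-hand end of the
# front).

#' Hyperparameter search space
#'
#' A finite set of per-hyperparameter domains over the searchable fields of
#' [detector_config()], plus a builder turning one assignment into a config.
#'
#' @param dims Named list of value vectors (discrete domains).
#' @param build Function taking a named list (one value per dim) and
#'   returning a [detector_config()]. The default builder passes matching
#'   names straight to `detector_config()` and understands the compound dim
#'   `conv_blocks` given as a list of block lists.
#' @return An object of class `"search_space"`.
#' @export
#' @examples
#' sp <- search_space(list(gru_hidden = c(8, 16, 32), dilation_k = c(1, 8)))
#' cfg <- sample_config(sp, seed = 1)
search_space <- function(dims, build = NULL) {
  stopifnot(is.list(dims), length(dims) >= 1, !is.null(names(dims)))
  build <- build %||% function(assign) {
    do.call(detector_config, assign)
  }
  structure(list(dims = dims, build = build), class = "search_space")
}

#' Default detector search space
#'
#' A compact space over window length, convolutional width, recurrent width
#' and time dilation, all yielding buildable single-input configs.
#'
#' @return A [search_space()].
#' @export
default_search_space <- function() {
  search_space(list(
    window_samples = c(32, 54, 80),
    conv_channels = c(4, 8, 16),
    gru_hidden = c(8, 16, 32, 64),
    dilation_k = c(1, 4, 8)
  ), build = function(a) {
    detector_config(
      window_samples = a$window_samples,
      conv_blocks = list(c(a$conv_channels, 7, 2), c(2 * a$conv_channels, 5, 2)),
      gru_hidden = a$gru_hidden, dilation_k = a$dilation_k
    )
  })
}

# All assignments of a (small) space, in deterministic lexicographic order.
enumerate_space <- function(space) {
  grid <- expand.grid(lapply(space$dims, seq_along))
  lapply(seq_len(nrow(grid)), function(i) {
    a <- lapply(seq_along(space$dims), function(j) {
      space$dims[[j]][[grid[i, j]]]
    })
    names(a) <- names(space$dims)
    a
  })
}

#' Draw one assignment from a search space
#'
#' @param space A [search_space()].
#' @param seed RNG seed.
#' @return A named assignment list (pass through `space$build` for the
#'   config).
#' @export
sample_config <- function(space, seed = 1) {
  with_seed(seed, {
    a <- lapply(space$dims, function(v) v[[sample.int(length(v), 1L)]])
    names(a) <- names(space$dims)
    a
  })
}

assignment_key <- function(a) paste(vapply(a, function(x) {
  paste(format(x), collapse = "_")
}, character(1)), collapse = "|")

# Numeric encoding for the surrogate: scaled value per numeric dim, one-hot
# per non-numeric dim.
encode_assignment <- function(a, space) {
  unlist(lapply(names(space$dims), function(nm) {
    dom <- space$dims[[nm]]
    if (is.numeric(dom)) {
      lo <- min(dom); hi <- max(dom)
      if (hi > lo) (a[[nm]] - lo) / (hi - lo) else 0
    } else {
      as.numeric(vapply(dom, identical, logical(1), a[[nm]]))
    }
  }))
}

#' Pareto candidate point
#'
#' @param assignment Named hyperparameter assignment.
#' @param hw_cost Hardware cost: trainable-parameter count (integer >= 0).
#' @param sw_cost Software cost: `1 - f1` of the trained model, in `[0, 1]`.
#' @return An object of class `"pareto_point"`.
#' @export
pareto_point <- function(assignment, hw_cost, sw_cost) {
  stopifnot(hw_cost >= 0, sw_cost >= 0, sw_cost <= 1)
  structure(list(assignment = assignment, hw_cost = as.numeric(hw_cost),
                 sw_cost = as.numeric(sw_cost)),
            class = "pareto_point")
}

#' Pareto domination
#'
#' `a` dominates `b` iff `a` is no worse on both costs and strictly better
#' on at least one. A point never dominates itself.
#'
#' @param a,b [pareto_point()]s.
#' @return Logical.
#' @export
dominates <- function(a, b) {
  (a$hw_cost <= b$hw_cost && a$sw_cost <= b$sw_cost) &&
    (a$hw_cost < b$hw_cost || a$sw_cost < b$sw_cost)
}

#' Update a Pareto front with a new point
#'
#' Inserts the point iff no member dominates it, evicting members it
#' dominates; the result equals brute-force non-dominated filtering of all
#' points ever streamed in. The front stays sorted by hardware cost.
#'
#' @param front List of non-dominated [pareto_point()]s.
#' @param point A [pareto_point()].
#' @return The updated front.
#' @export
update_front <- function(front, point) {
  if (any(vapply(front, dominates, logical(1), b = point))) return(front)
  keep <- !vapply(front, function(f) dominates(point, f), logical(1))
  front <- c(front[keep], list(point))
  front[order(vapply(front, `[[`, numeric(1), "hw_cost"),
              vapply(front, `[[`, numeric(1), "sw_cost"))]
}

#' Brute-force non-dominated filter
#'
#' Quadratic reference filter over a full point cloud; the streaming
#' [update_front()] must agree with it.
#'
#' @param points List of [pareto_point()]s.
#' @return The non-dominated subset sorted by hardware cost.
#' @export
pareto_filter <- function(points) {
  keep <- vapply(seq_along(points), function(i) {
    !any(vapply(points, dominates, logical(1), b = points[[i]])[-i])
  }, logical(1))
  pts <- points[keep]
  pts[order(vapply(pts, `[[`, numeric(1), "hw_cost"),
            vapply(pts, `[[`, numeric(1), "sw_cost"))]
}

#' Fit / query the software-cost surrogate
#'
#' A linear regression meta-model over encoded assignments. With fewer
#' completed evaluations than coefficients (or a rank-deficient design) it
#' falls back to the history mean; with no history it predicts the
#' uninformative prior 0.5. Predictions are clipped to `[0, 1]`.
#'
#' @param history List of evaluated [pareto_point()]s.
#' @param space The [search_space()].
#' @return An object of class `"pmbo_surrogate"`.
#' @export
fit_surrogate <- function(history, space) {
  obj <- list(space = space, kind = "prior", mean = 0.5, coef = NULL)
  if (length(history) >= 1) {
    y <- vapply(history, `[[`, numeric(1), "sw_cost")
    X <- t(vapply(history, function(p) {
      encode_assignment(p$assignment, space)
    }, numeric(length(encode_assignment(history[[1]]$assignment, space)))))
    obj$mean <- mean(y)
    obj$kind <- "mean"
    if (length(history) >= ncol(X) + 2L) {
      Xd <- cbind(1, X)
      fit <- lm.fit(Xd, y)
      if (fit$rank == ncol(Xd) && all(is.finite(fit$coefficients))) {
        obj$coef <- fit$coefficients
        obj$kind <- "linear"
      }
    }
  }
  structure(obj, class = "pmbo_surrogate")
}

#' @param surrogate A `"pmbo_surrogate"`.
#' @param assignment A named assignment from the same space.
#' @rdname fit_surrogate
#' @export
predict_surrogate <- function(surrogate, assignment) {
  p <- if (surrogate$kind == "linear") {
    sum(c(1, encode_assignment(assignment, surrogate$space)) * surrogate$coef)
  } else {
    surrogate$mean
  }
  min(max(p, 0), 1)
}

#' Propose the next configuration to evaluate
#'
#' Epsilon-greedy acquisition: with probability `explore_eps`, sample
#' uniformly from the space; otherwise draw `m` candidates and return the one
#' with the lowest predicted software cost. Hardware cost is computed
#' analytically and never predicted. Already-evaluated assignments (by key)
#' are excluded.
#'
#' @param surrogate A fitted surrogate (or `NULL` for pure exploration).
#' @param space A [search_space()].
#' @param explore_eps Exploration probability in `[0, 1]`.
#' @param seed Proposal seed (fixed at proposal time for reproducibility).
#' @param m Candidate pool size for the greedy branch (default 16).
#' @param exclude Character vector of assignment keys to avoid.
#' @return A named assignment, or `NULL` if the space is exhausted.
#' @export
propose <- function(surrogate, space, explore_eps = 0.2, seed = 1, m = 16L,
                    exclude = character()) {
  all_asn <- enumerate_space(space)
  keys <- vapply(all_asn, assignment_key, character(1))
  avail <- all_asn[!keys %in% exclude]
  if (!length(avail)) return(NULL)
  with_seed(seed, {
    if (runif(1) < explore_eps || is.null(surrogate) ||
        surrogate$kind == "prior") {
      avail[[sample.int(length(avail), 1L)]]
    } else {
      cand <- avail[sample.int(length(avail), min(m, length(avail)),
                               replace = FALSE)]
      pred <- vapply(cand, function(a) predict_surrogate(surrogate, a),
                     numeric(1))
      cand[[which.min(pred)]]
    }
  })
}

#' Run the Pareto search
#'
#' Evaluates up to `budget` distinct configurations. Proposals are committed
#' in rounds of `n_workers` (emulating parallel workers evaluating
#' independent configs); each evaluation's seed is fixed at proposal time,
#' and the surrogate is refit whenever a round of results arrives. A trainer
#' failure marks the config failed and the search continues. The selected
#' configuration is the front member with minimal software cost.
#'
#' @param space A [search_space()].
#' @param budget Total number of evaluations.
#' @param trainer Callback `function(config, seed)` returning the trained
#'   model's f1 in `[0, 1]`.
#' @param n_workers Proposals per round (default 1).
#' @param explore_eps Exploration probability (default 0.2).
#' @param seed Master seed.
#' @return `list(history, failed, front, selected)`; `history` is a list of
#'   evaluated [pareto_point()]s (in commit order), `selected` the winning
#'   assignment with its costs.
#' @export
run_search <- function(space, budget, trainer, n_workers = 1L,
                       explore_eps = 0.2, seed = 1) {
  stopifnot(budget >= 1, n_workers >= 1)
  history <- list()
  failed <- list()
  front <- list()
  surrogate <- fit_surrogate(list(), space)
  done_keys <- character()
  n_prop <- 0L
  while (n_prop < budget) {
    round_n <- min(n_workers, budget - n_prop)
    proposals <- list()
    for (j in seq_len(round_n)) {
      prop_seed <- derive_seed(seed, n_prop + j)
      a <- propose(surrogate, space, explore_eps, seed = prop_seed,
                   exclude = done_keys)
      if (is.null(a)) break
      done_keys <- c(done_keys, assignment_key(a))
      proposals[[length(proposals) + 1L]] <-
        list(assignment = a, eval_seed = prop_seed)
    }
    if (!length(proposals)) break
    n_prop <- n_prop + length(proposals)
    for (p in proposals) {
      cfg <- space$build(p$assignment)
      hw <- count_parameters(cfg)
      f1 <- tryCatch(trainer(cfg, p$eval_seed), error = function(e) e)
      if (inherits(f1, "error")) {
        failed[[length(failed) + 1L]] <-
          list(assignment = p$assignment, error = conditionMessage(f1))
        next
      }
      pt <- pareto_point(p$assignment, hw, 1 - f1)
      history[[length(history) + 1L]] <- pt
      front <- update_front(front, pt)
    }
    surrogate <- fit_surrogate(history, space)
  }
  selected <- NULL
  if (length(front)) {
    sw <- vapply(front, `[[`, numeric(1), "sw_cost")
    selected <- front[[which.min(sw)]]
  }
  list(history = history, failed = failed, front = front, selected = selected)
}

#' Export a front as a data frame
#'
#' @param front List of [pareto_point()]s.
#' @return Data frame with `hw_cost`, `sw_cost` and the assignment columns.
#' @export
front_table <- function(front) {
  if (!length(front)) {
    return(data.frame(hw_cost = numeric(), sw_cost = numeric()))
  }
  asn <- do.call(rbind, lapply(front, function(p) {
    as.data.frame(p$assignment, stringsAsFactors = FALSE)
  }))
  cbind(data.frame(hw_cost = vapply(front, `[[`, numeric(1), "hw_cost"),
                   sw_cost = vapply(front, `[[`, numeric(1), "sw_cost")),
        asn)
}
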
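# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a per-module child seed from a master seed. Documented fan-out
# scheme: golden-ratio hashing of (master, stream index), folded into the
# 32-bit signed integer range R accepts in set.seed().
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L)
  idx <- if (is.character(stream)) {
    sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  } else as.numeric(stream)
  x <- (as.numeric(master) * 2654435761 + idx * 40503) %% 2147483647
  as.integer(x) + 1L
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
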
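# Internal helpers: seeded evaluation and small validators.

# Evaluate `code` under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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

# Deterministically derive an independent stream seed from a root seed.
# Kept below 2^31 - 1; distinct stream ids give well-separated seeds so adding
# draws in one stream never perturbs another.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  for (k in seq_len(stream + 1)) {
    s <- (s * 48271 + 1299709) %% m
  }
  as.integer(s)
}

stop_if_not_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
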
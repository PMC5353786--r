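# Shared internal helpers: seeded RNG scoping and sub-seed derivation.

# Derive a reproducible 31-bit sub-seed from a base seed and a stage offset.
# Lehmer step keeps values in [1, 2^31 - 2] so set.seed() is always valid.
derive_seed <- function(seed, offset = 0L) {
  m <- 2147483647
  x <- (as.double(seed) %% m + 1) * 48271 + as.double(offset) * 16807
  as.integer(x %% (m - 1)) + 1L
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %s", name, min))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}
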
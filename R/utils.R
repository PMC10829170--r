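# Shared helpers: scoped RNG and seed derivation.

# Run `expr` under a private RNG stream so library calls never disturb the
# caller's random state. Mersenne-Twister, rounding discard for sampling.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one master seed, kept within the 32-bit
# signed integer range. Distinct `what` strings give independent streams.
derive_seed <- function(seed, what, k = 0L) {
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((as.numeric(seed) * 7919 + h * 131 + k) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
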
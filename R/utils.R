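# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic operations in the package go
# through this, so outputs are pure functions of their explicit seeds.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed), seed >= 0)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic sub-seed derivation: keeps every derived seed a positive
# 31-bit integer.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483629L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
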
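# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards. Keeps every stochastic operation reproducible
# without clobbering the session RNG.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic child seed derived from a master seed and an index; stays
# within the 32-bit signed integer range.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 1000003 + index * 7919) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
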
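# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL means: use the current RNG stream as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed for stage `offset` of a run seeded with `seed`.
# Kept strictly below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) %% 1000003) * 2039 + 7 * offset) %% 2147483629L
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
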
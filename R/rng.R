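# Independent reproducible RNG substreams.
#
# Each stimulus owns one master seed; init, lifetime and respawn draws come
# from separate substreams so that, e.g., changing the lifetime draws cannot
# perturb the initial dot layout. A substream is simply a saved .Random.seed
# that is swapped in around its draws and swapped out again, leaving the
# global RNG untouched.

new_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  env
}

with_stream <- function(stream, expr) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  eval.parent(substitute(expr))
}

# deterministic derived seeds, kept within 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1103515245 + k * 12345) %% 2147483647)
}
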
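# Internal helpers.

# Scoped RNG: seed the generator for a deterministic computation and hand
# back a restore() that reinstates the caller's RNG state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

# Circular distance between two positions on a genome of given length.
circular_distance <- function(a, b, length) {
  d <- abs(a - b) %% length
  pmin(d, length - d)
}
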
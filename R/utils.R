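# Internal RNG helpers: every stochastic step draws from a substream derived
# deterministically from one user seed, and the caller's RNG state is restored.

derive_seed <- function(seed, offset) {
  # Lehmer-style mix, kept inside 32-bit signed integer range
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483647)
}

with_seed <- function(seed, expr) {
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
  expr
}
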
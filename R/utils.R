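# Internal reproducibility helpers.  All randomness in the package flows
# through seeds derived from a single user-facing seed, evaluated without
# disturbing the caller's RNG state.

# Mix a base seed with integer stream identifiers into a 31-bit seed.
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) {
    h <- (h * 69069 + (as.numeric(k) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under set.seed(seed), restoring the global RNG state after.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
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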
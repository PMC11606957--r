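# internal helpers shared across modules

# Run code under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stream of per-item seeds from a master seed, kept within the
# 32-bit signed range R uses for set.seed().
deriveSeeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  as.integer((as.numeric(seed) + 7919 * seq_len(n)) %% 2147483647)
}

# Seed arithmetic kept inside R's 32-bit signed integer range.
seedOffset <- function(seed, k) {
  as.integer((as.numeric(seed) + as.numeric(k)) %% 2147483647)
}

# Accept a FundusImage or a bare numeric matrix.
asPixels <- function(x) {
  if (is(x, "FundusImage")) return(x@pixels)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a FundusImage or a numeric matrix")
}

stopifnotScalarCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("%s must be a single integer >= %d", name, min))
}
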
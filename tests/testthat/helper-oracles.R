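# shared fixtures and independent oracles

randImage <- function(n = 128L, seed = 1L) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}

# brute-force Moore-Penrose solve via an independent implementation
pinvSolveOracle <- function(H, Tm) {
  MASS::ginv(H) %*% Tm
}

# deterministic small two-class problem in feature space
cloudFixture <- function(n = 30L, d = 6L, sep = 8, seed = 1L) {
  generateFeatureClouds(n, d, sep, seed = seed)
}
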
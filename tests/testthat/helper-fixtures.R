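## Build a valid NeighborTable directly from a distance matrix (M x k),
## for tests that exercise distance-only estimators on hand-picked
## distance profiles. Neighbor indices are filled with an arbitrary
## non-self pattern; the estimators under test never use them.
syntheticNT <- function(D) {
  D <- as.matrix(D)
  m <- nrow(D)
  idx <- matrix(rep((seq_len(m) %% max(m, 2L)) + 1L, ncol(D)), m)
  new("NeighborTable", k = ncol(D), indices = idx, distances = D)
}

ballPoints <- function(d, n, seed = 0) {
  samplePoints(generateManifold("hyperball", n, list(d = d), seed = seed))
}

## Random orthogonal matrix (seeded), for rigid-motion invariance checks.
randomRotation <- function(p, seed = 0) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(p * p), p)))
}
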
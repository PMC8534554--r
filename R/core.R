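## Internal constructor: classify a raw numeric result into a status.
## "ok" iff finite and > 0; NaN/NA, negative and infinite results keep a
## machine-readable status instead of leaking through as bare NaN.
newIDEstimate <- function(method, value, params = list(),
                          nUsed = NA_integer_, degenerate = FALSE) {
  raw <- if (length(value) == 1L) as.numeric(value) else NA_real_
  if (degenerate) {
    status <- "degenerate_input"
    val <- NA_real_
  } else if (is.na(raw)) {
    status <- "invalid_nan"
    val <- NA_real_
  } else if (is.infinite(raw)) {
    status <- "invalid_infinite"
    val <- NA_real_
  } else if (raw <= 0) {
    status <- "invalid_negative"
    val <- raw
  } else {
    status <- "ok"
    val <- raw
  }
  new("IDEstimate", method = method, value = val, status = status,
      params = params, nUsed = as.integer(nUsed))
}

#' Exact k-nearest-neighbor table
#'
#' Computes, for every observation, its `k` exact nearest neighbors under
#' the Euclidean metric by brute force. Ties are broken by lower row index
#' so the result is fully deterministic; a point is never its own
#' neighbor. Duplicate points (zero distances) are permitted and kept in
#' the table -- each downstream estimator decides whether zero distances
#' make its input degenerate.
#'
#' @param X Numeric matrix (observations x features).
#' @param k Number of neighbors, `1 <= k <= nrow(X) - 1`.
#' @param metric Distance metric; only `"euclidean"` is implemented (the
#'   argument is an extension point).
#' @return A [NeighborTable-class].
#' @examples
#' nt <- buildNeighborTable(cbind(c(0, 1, 2)), k = 1)
#' neighborDistances(nt)  # all 1 on a unit grid
#' @export
buildNeighborTable <- function(X, k, metric = c("euclidean")) {
  metric <- match.arg(metric)
  X <- asDataMatrix(X)
  k <- as.integer(k)
  if (k < 1L) stop("k must be positive")
  if (k >= nrow(X)) stop("k must be at most nrow(X) - 1")
  res <- .cpp_knn(X, k)
  new("NeighborTable", k = k, indices = res$indices,
      distances = res$distances)
}

#' Covariance eigenvalue spectrum
#'
#' Eigenvalues of the sample covariance matrix of the mean-centered data,
#' using the 1/(M-1) normalization, sorted non-increasing. Eigenvalues
#' below `1e-12 * lambda_1` (numerical noise) are clamped to zero. A
#' constant matrix yields an all-zero spectrum, which the PCA criteria
#' then report as degenerate input.
#'
#' @param X Numeric matrix (observations x features), `M >= 2`.
#' @return An [EigenSpectrum-class].
#' @examples
#' # a 1-D line embedded in 3-D has exactly one nonzero eigenvalue
#' t <- seq(0, 1, length.out = 50)
#' eigenvalues(covarianceSpectrum(cbind(t, 2 * t, -t)))
#' @export
covarianceSpectrum <- function(X) {
  X <- asDataMatrix(X)
  Xc <- sweep(X, 2L, colMeans(X), "-")
  ## eigen of crossprod avoids forming cov() twice for wide inputs
  l <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE,
             only.values = TRUE)$values
  l[l < 0] <- 0
  if (l[1] > 0) l[l < 1e-12 * l[1]] <- 0
  new("EigenSpectrum", lambdas = l)
}

#' Standard preprocessing for ID estimation
#'
#' Applies the standard cleaning pipeline: per-feature min/max scaling to
#' the unit interval (constant features map to 0), removal of approximate
#' non-unique columns and rows (a column/row is dropped when its maximum
#' absolute difference to an earlier one is at most `dedupTol`; the first
#' occurrence is kept), and seeded uniform row subsampling when the matrix
#' exceeds `maxRows`. Identical or near-identical rows and columns distort
#' several nearest-neighbor and spectrum estimators, which is why they are
#' filtered before estimation.
#'
#' @param X Numeric matrix.
#' @param scale Min/max scale each feature to `[0, 1]`?
#' @param dedupTol Tolerance for approximate duplicates (Chebyshev
#'   distance, applied after scaling). `0` removes exact duplicates only.
#' @param maxRows Maximum number of rows kept; above it, rows are
#'   subsampled uniformly at random with `seed`.
#' @param seed Integer seed for the subsampling step.
#' @return The cleaned numeric matrix.
#' @examples
#' preprocessMatrix(cbind(c(2, 4, 6)))  # -> 0, 0.5, 1
#' @export
preprocessMatrix <- function(X, scale = TRUE, dedupTol = 1e-8,
                             maxRows = 100000L, seed = 0L) {
  X <- asDataMatrix(X)
  if (scale) {
    rng <- apply(X, 2L, range)
    span <- rng[2L, ] - rng[1L, ]
    span[span == 0] <- 1  # constant feature -> 0 after shift
    X <- sweep(sweep(X, 2L, rng[1L, ], "-"), 2L, span, "/")
  }
  if (dedupTol >= 0) {
    keepC <- .cpp_dedup_rows(t(X), dedupTol)
    X <- X[, keepC, drop = FALSE]
    keepR <- .cpp_dedup_rows(X, dedupTol)
    X <- X[keepR, , drop = FALSE]
  }
  if (nrow(X) < 2L)
    stop("degenerate input: fewer than 2 distinct rows remain")
  if (nrow(X) > maxRows) {
    sel <- withSeed(seed, sort(sample.int(nrow(X), maxRows)))
    X <- X[sel, , drop = FALSE]
  }
  X
}

#' Repurpose a global estimator as a local, per-point estimator
#'
#' For every observation, applies a global estimator to the sub-cloud
#' formed by the point and its `k` nearest neighbors, yielding a per-point
#' local intrinsic dimension. Regions of constant local ID can segment a
#' point cloud into parts of different dimensionality. Per-point failures
#' carry a status code rather than a silent NaN. Neighborhood-based
#' parameters of the wrapped method are clamped to the sub-cloud size.
#'
#' @param X Numeric matrix.
#' @param method Registered global method tag (see [listMethods()]).
#' @param k Neighborhood size; `k + 1 <= nrow(X)`. With `k = nrow(X) - 1`
#'   every local value equals the global estimate.
#' @param params Named list of parameter overrides for the method.
#' @param seed Integer seed passed to stochastic methods.
#' @return A [LocalIDField-class].
#' @examples
#' ldb <- lineDiskBall(c(150, 150, 150), seed = 0)
#' fld <- estimateLocal(samplePoints(ldb), "lPCA_FO", k = 40)
#' tapply(round(idValue(fld)), segmentLabels(ldb), mean)
#' @export
estimateLocal <- function(X, method, k, params = list(), seed = 0L) {
  X <- asDataMatrix(X)
  k <- as.integer(k)
  if (k + 1L > nrow(X)) stop("k + 1 must be at most nrow(X)")
  nt <- buildNeighborTable(X, k)
  m <- nrow(X)
  values <- rep(NA_real_, m)
  statuses <- rep("invalid_nan", m)
  for (i in seq_len(m)) {
    sub <- X[c(i, nt@indices[i, ]), , drop = FALSE]
    est <- tryCatch(
      estimateGlobal(sub, method, params = params, seed = seed,
                     .clamp = TRUE),
      error = function(e) newIDEstimate(method, NA_real_,
                                        degenerate = TRUE))
    values[i] <- est@value
    statuses[i] <- est@status
  }
  new("LocalIDField", values = values, statuses = statuses, k = k,
      method = method)
}
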
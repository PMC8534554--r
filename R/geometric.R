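## Accept either a data matrix or a prebuilt NeighborTable; slice or build
## so that exactly k neighbor columns are available.
.asNeighborTable <- function(x, k) {
  if (is(x, "NeighborTable")) {
    if (x@k < k) stop("NeighborTable has fewer than k = ", k, " neighbors")
    if (x@k == k) return(x)
    return(new("NeighborTable", k = as.integer(k),
               indices = x@indices[, seq_len(k), drop = FALSE],
               distances = x@distances[, seq_len(k), drop = FALSE]))
  }
  buildNeighborTable(x, k)
}

#' Correlation (fractal) dimension
#'
#' Two-scale correlation-integral estimator. The correlation integral
#' `C(r) = 2/(M(M-1)) * #\{pairs with d_ij <= r\}` scales as `r^d` on a
#' d-dimensional support; the dimension is the log-log slope between two
#' scales `r1`, `r2`, taken as the mean distance to the `k1`-th and
#' `k2`-th nearest neighbor. Pair counts are exact (brute force over all
#' pairs), and the estimate is invariant to rescaling the data.
#'
#' @param X Numeric matrix, `nrow(X) >= k2 + 1`.
#' @param k1,k2 Neighbor orders defining the two scales (`k1 < k2`).
#' @return An [IDEstimate-class] tagged `"CorrInt"`. Coincident scales or
#'   an empty correlation integral give `"degenerate_input"`.
#' @examples
#' X <- samplePoints(generateManifold("hyperball", 400, list(d = 2),
#'                                    seed = 1))
#' idValue(corrInt(X))
#' @export
corrInt <- function(X, k1 = 10L, k2 = 20L) {
  X <- asDataMatrix(X)
  k1 <- as.integer(k1); k2 <- as.integer(k2)
  if (k1 >= k2) stop("k1 must be smaller than k2")
  if (nrow(X) < k2 + 1L) stop("need at least k2 + 1 rows")
  m <- nrow(X)
  nt <- buildNeighborTable(X, k2)
  r1 <- mean(nt@distances[, k1])
  r2 <- mean(nt@distances[, k2])
  params <- list(k1 = k1, k2 = k2, r1 = r1, r2 = r2)
  counts <- .cpp_count_pairs(X, c(r1, r2))
  if (r1 == r2 || counts[1] == 0)
    return(newIDEstimate("CorrInt", NA_real_, params, m,
                         degenerate = TRUE))
  cc <- counts * 2 / (m * (m - 1))
  d <- (log(cc[2]) - log(cc[1])) / (log(r2) - log(r1))
  newIDEstimate("CorrInt", d, params, m)
}

#' Maximum-likelihood intrinsic dimension
#'
#' The nearest-neighbor maximum-likelihood estimator. Per point `x` the
#' inverse estimate is `m(x) = (1/(k-1)) * sum_{j<k} ln(r_k(x)/r_j(x))`;
#' the two aggregations are the bias-corrected global form (average the
#' inverse estimates over all points and neighbor ranks, then invert --
#' the default) and the plain mean of the per-point estimates `1/m(x)`.
#' Zero neighbor distances (duplicate points) make the log ratios
#' undefined and are reported as degenerate input.
#'
#' @param x Numeric matrix or a [NeighborTable-class].
#' @param k Number of neighbors (default 20, `k >= 2`).
#' @param aggregate `"global_mackay"` (invert the averaged inverse) or
#'   `"mean_of_locals"`.
#' @return An [IDEstimate-class] tagged `"MLE"`.
#' @examples
#' X <- samplePoints(generateManifold("hyperball", 500, list(d = 3),
#'                                    seed = 1))
#' idValue(mleID(X))
#' @export
mleID <- function(x, k = 20L,
                  aggregate = c("global_mackay", "mean_of_locals")) {
  aggregate <- match.arg(aggregate)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  nt <- .asNeighborTable(x, k)
  D <- nt@distances
  m <- nrow(D)
  params <- list(k = k, aggregate = aggregate)
  if (any(D[, seq_len(k - 1L)] == 0) || any(D[, k] == 0))
    return(newIDEstimate("MLE", NA_real_, params, m, degenerate = TRUE))
  ## log(r_k / r_j) for j = 1..k-1, all points
  lr <- log(D[, k] / D[, seq_len(k - 1L), drop = FALSE])
  if (all(lr == 0))
    return(newIDEstimate("MLE", NA_real_, params, m, degenerate = TRUE))
  d <- if (aggregate == "global_mackay") 1 / mean(lr)
       else mean(1 / rowMeans(lr))
  newIDEstimate("MLE", d, params, m)
}

#' Two-nearest-neighbors dimension estimator
#'
#' Uses only the ratio `mu_i = r_2(x_i) / r_1(x_i)` of the first two
#' neighbor distances, which on a d-dimensional support follows a Pareto
#' law with shape `d`. The largest `discardFraction` of the ratios (tail
#' outliers, where density varies most) is discarded. The default fit is
#' the linear one: the slope through the origin of
#' `-ln(1 - F(mu_(i)))` against `ln mu_(i)` with the empirical CDF at
#' plotting position `i/M`; the `"mle"` fit is `M' / sum(ln mu_i)` over
#' retained points.
#'
#' @param x Numeric matrix or a [NeighborTable-class] (needs 2 neighbor
#'   columns).
#' @param discardFraction Fraction of largest ratios discarded
#'   (default 0.1).
#' @param fit `"linear"` (default) or `"mle"`.
#' @return An [IDEstimate-class] tagged `"TwoNN"`. `r_1 = 0` anywhere, or
#'   all ratios equal to 1, give `"degenerate_input"`.
#' @examples
#' X <- samplePoints(generateManifold("hypercube", 1000, list(d = 2),
#'                                    seed = 1))
#' idValue(twoNN(X))
#' @export
twoNN <- function(x, discardFraction = 0.1, fit = c("linear", "mle")) {
  fit <- match.arg(fit)
  stopifnot(discardFraction >= 0, discardFraction < 1)
  nt <- .asNeighborTable(x, 2L)
  D <- nt@distances
  m <- nrow(D)
  params <- list(discardFraction = discardFraction, fit = fit)
  if (any(D[, 1L] == 0))
    return(newIDEstimate("TwoNN", NA_real_, params, m, degenerate = TRUE))
  mu <- D[, 2L] / D[, 1L]
  if (all(mu == 1))
    return(newIDEstimate("TwoNN", NA_real_, params, m, degenerate = TRUE))
  ord <- sort(mu)
  nKeep <- m - ceiling(discardFraction * m)
  if (nKeep < 2L)
    return(newIDEstimate("TwoNN", NA_real_, params, m, degenerate = TRUE))
  d <- if (fit == "mle") {
    s <- sum(log(ord[seq_len(nKeep)]))
    if (s == 0) NA_real_ else nKeep / s
  } else {
    i <- seq_len(nKeep)
    xs <- log(ord[i])
    ys <- -log(1 - i / m)
    use <- is.finite(ys) & xs > 0
    if (!any(use)) NA_real_
    else sum(xs[use] * ys[use]) / sum(xs[use]^2)
  }
  newIDEstimate("TwoNN", d, params, m)
}

#' Manifold-adaptive dimension estimator
#'
#' Per point, compares the distance to the k-th and to the
#' `ceiling(k/2)`-th neighbor: doubling the neighbor count scales the
#' neighborhood radius by `2^(1/d)` on a d-dimensional support, so
#' `d(x) = ln 2 / ln(r_k(x) / r_{k/2}(x))`. Points with tied radii are
#' invalid (division by zero) and excluded; the invalid fraction is
#' reported in the params, and the estimate itself is only degenerate
#' when no point is valid.
#'
#' @param x Numeric matrix or a [NeighborTable-class].
#' @param k Number of neighbors (default 20; even values pair the two
#'   radii exactly).
#' @param aggregate `"mean"` (default) or `"median"` over valid points.
#' @return An [IDEstimate-class] tagged `"MADA"`, with
#'   `params$invalidFraction` recording the share of invalid points.
#' @examples
#' X <- samplePoints(generateManifold("hyperball", 500, list(d = 2),
#'                                    seed = 1))
#' idValue(mada(X))
#' @export
mada <- function(x, k = 20L, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  nt <- .asNeighborTable(x, k)
  D <- nt@distances
  m <- nrow(D)
  kh <- as.integer(ceiling(k / 2))
  local <- log(2) / log(D[, k] / D[, kh])
  valid <- is.finite(local) & local > 0
  params <- list(k = k, aggregate = aggregate,
                 invalidFraction = mean(!valid))
  if (!any(valid))
    return(newIDEstimate("MADA", NA_real_, params, m, degenerate = TRUE))
  d <- if (aggregate == "mean") mean(local[valid]) else
    stats::median(local[valid])
  newIDEstimate("MADA", d, params, m)
}

#' Method-of-moments dimension estimator
#'
#' Per point, matches the first moment of the neighbor distances to its
#' expectation under local uniformity: with `w = r_k` and
#' `m1 = mean(r_1..r_k)`, `E[m1/w] = d/(d+1)`, giving
#' `d(x) = m1 / (w - m1)`. Points whose distances are all equal are
#' invalid; the global estimate is the mean over valid points.
#'
#' @param x Numeric matrix or a [NeighborTable-class].
#' @param k Number of neighbors (default 20).
#' @return An [IDEstimate-class] tagged `"MOM"`, with
#'   `params$invalidFraction`.
#' @examples
#' X <- samplePoints(generateManifold("hyperball", 500, list(d = 2),
#'                                    seed = 1))
#' idValue(momID(X))
#' @export
momID <- function(x, k = 20L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  nt <- .asNeighborTable(x, k)
  D <- nt@distances
  m <- nrow(D)
  w <- D[, k]
  m1 <- rowMeans(D)
  local <- m1 / (w - m1)
  valid <- is.finite(local) & local > 0
  params <- list(k = k, invalidFraction = mean(!valid))
  if (!any(valid))
    return(newIDEstimate("MOM", NA_real_, params, m, degenerate = TRUE))
  newIDEstimate("MOM", mean(local[valid]), params, m)
}

## Per-point tight-locality estimate. A is the k x p matrix of neighbor
## offsets from the query point, dd their norms, r the neighborhood
## radius. For each ordered neighbor pair (v, w) -- and additionally the
## mirrored target 2x - w, which reduces boundary bias -- the term is the
## log of the pair distance over the distance from v to the boundary of
## the k-NN ball along the ray through the target. Under local uniformity
## that normalized distance to the power d is U(0,1), so the estimate is
## the negative reciprocal of the mean log term (a Hill-type estimator
## over all pairs).
.tlePoint <- function(A, dd, r) {
  G <- tcrossprod(A)
  n2 <- dd^2
  terms <- numeric(0)
  for (sgn in c(1, -1)) {
    D2 <- outer(n2, n2, "+") - 2 * sgn * G
    D2[D2 < 0] <- 0
    D <- sqrt(D2)
    off <- (D > 0) & !diag(TRUE, nrow(D2))
    s <- (sgn * G - n2) / D           # <a_i, u> along the ray
    disc <- s^2 + r^2 - n2
    disc[disc < 0] <- 0
    tt <- -s + sqrt(disc)             # distance from v to ball boundary
    ## both points lie inside the ball, so D <= tt up to rounding; all
    ## pairs are kept so the term set is stable under rigid motions and
    ## rescaling
    okp <- off & is.finite(tt) & tt > 0
    if (any(okp)) terms <- c(terms, log(D[okp] / tt[okp]))
  }
  terms <- terms[is.finite(terms)]
  if (!length(terms)) return(NA_real_)
  -1 / mean(terms)
}

#' Tight-locality dimension estimator
#'
#' Estimates dimension from distance ratios inside each k-nearest-neighbor
#' ball, using every ordered pair of neighbors (and their reflections
#' about the query point) as viewpoint--target pairs: each pair
#' contributes the log of its distance normalized by the distance from the
#' viewpoint to the ball boundary along the ray through the target, and
#' the per-point estimate is the negative reciprocal of the averaged log
#' terms. Using all pairs extracts far more distance information from a
#' tight locality than the query-centered ratios alone. Points with
#' coincident neighbors or a non-positive estimate are counted invalid
#' (`params$invalidFraction`); the global estimate is the mean over valid
#' points.
#'
#' @param X Numeric matrix (coordinates are required, not just
#'   distances).
#' @param k Number of neighbors (default 20, `k >= 3`).
#' @return An [IDEstimate-class] tagged `"TLE"`.
#' @examples
#' X <- samplePoints(generateManifold("hyperball", 500, list(d = 2),
#'                                    seed = 1))
#' idValue(tleID(X))
#' @export
tleID <- function(X, k = 20L) {
  X <- asDataMatrix(X)
  k <- as.integer(k)
  if (k < 3L) stop("k must be at least 3")
  nt <- buildNeighborTable(X, k)
  m <- nrow(X)
  local <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    r <- nt@distances[i, k]
    if (r == 0) next
    A <- X[nt@indices[i, ], , drop = FALSE] -
      matrix(X[i, ], k, ncol(X), byrow = TRUE)
    local[i] <- .tlePoint(A, nt@distances[i, ], r)
  }
  valid <- is.finite(local) & local > 0
  params <- list(k = k, invalidFraction = mean(!valid))
  if (!any(valid))
    return(newIDEstimate("TLE", NA_real_, params, m, degenerate = TRUE))
  newIDEstimate("TLE", mean(local[valid]), params, m)
}

## Log-likelihood of the minimum-neighbor-distance model for candidate
## dimension d, given rho = r_1/r_k in (0,1).
.mindLogLik <- function(d, rho, k) {
  sum(log(k * d) + (d - 1) * log(rho) + (k - 1) * log1p(-rho^d))
}

#' Minimum-neighbor-distance likelihood estimator
#'
#' Models the normalized first-neighbor distance `rho_i = r_1/r_k`, whose
#' density on a d-dimensional support is
#' `k d rho^(d-1) (1 - rho^d)^(k-1)`, and maximizes the joint likelihood
#' over the candidate dimension: over integers `1..DMax` (`"MLi"`) or
#' continuously on `[1, DMax]` by bounded scalar optimization (`"MLk"`).
#' Ratios equal to 0 or 1 carry no likelihood information and are dropped
#' (counted in `params$dropped`).
#'
#' @param x Numeric matrix or a [NeighborTable-class].
#' @param k Number of neighbors (default 10).
#' @param variant `"MLi"` (integer) or `"MLk"` (continuous).
#' @param DMax Candidate-dimension cap; defaults to the ambient dimension
#'   (required explicitly when `x` is a NeighborTable).
#' @return An [IDEstimate-class] tagged `"MiND_MLi"` or `"MiND_MLk"`.
#' @examples
#' X <- samplePoints(generateManifold("hyperball", 500, list(d = 3),
#'                                    seed = 1))
#' idValue(mindML(X))
#' @export
mindML <- function(x, k = 10L, variant = c("MLi", "MLk"), DMax = NULL) {
  variant <- match.arg(variant)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (is.null(DMax)) {
    if (is(x, "NeighborTable"))
      stop("DMax is required when x is a NeighborTable")
    DMax <- ncol(asDataMatrix(x))
  }
  DMax <- max(1L, as.integer(DMax))
  nt <- .asNeighborTable(x, k)
  D <- nt@distances
  m <- nrow(D)
  tag <- paste0("MiND_", variant)
  params <- list(k = k, DMax = DMax)
  if (any(D[, k] == 0))
    return(newIDEstimate(tag, NA_real_, params, m, degenerate = TRUE))
  rho <- D[, 1L] / D[, k]
  keep <- rho > 0 & rho < 1
  params$dropped <- sum(!keep)
  rho <- rho[keep]
  if (!length(rho))
    return(newIDEstimate(tag, NA_real_, params, m, degenerate = TRUE))
  d <- if (variant == "MLi") {
    ll <- vapply(seq_len(DMax), .mindLogLik, numeric(1), rho = rho, k = k)
    as.numeric(which.max(ll))
  } else {
    if (DMax == 1L) 1
    else optimize(.mindLogLik, c(1, DMax), rho = rho, k = k,
                  maximum = TRUE, tol = 1e-8)$maximum
  }
  newIDEstimate(tag, d, params, m)
}

#' k-NN graph scaling dimension estimator
#'
#' Uses the growth of the total edge length of the k-nearest-neighbor
#' graph with sample size: on a d-dimensional support the total weight
#' `L(n) = sum |e|^gamma` over graph edges scales as `n^a` with
#' `a = 1 - gamma/d`. For each subsample size, `nBoot` seeded subsamples
#' are drawn and the mean log total weight regressed on log size; the
#' dimension is `round(gamma / (1 - a))`, clamped to `[1, DMax]`.
#'
#' @param X Numeric matrix.
#' @param k Neighbors per graph node (default 5, `k < min(sizes)`).
#' @param gamma Edge-length exponent (default 1).
#' @param sizes Strictly increasing subsample sizes (default
#'   `round(M * c(0.25, 0.5, 1))`), maximum at most `nrow(X)`.
#' @param nBoot Subsamples per size (default 10).
#' @param seed Integer seed for subsampling.
#' @param DMax Dimension cap, default ambient dimension.
#' @return An [IDEstimate-class] tagged `"KNN"`; a fitted slope `a >= 1`
#'   is reported as invalid.
#' @examples
#' X <- samplePoints(generateManifold("hypercube", 600, list(d = 2),
#'                                    seed = 1))
#' idValue(knnGraphID(X, sizes = c(150, 300, 600)))
#' @export
knnGraphID <- function(X, k = 5L, gamma = 1, sizes = NULL, nBoot = 10L,
                       seed = 0L, DMax = NULL) {
  X <- asDataMatrix(X)
  m <- nrow(X)
  if (is.null(sizes)) sizes <- unique(pmax(k + 1L, round(m * c(0.25, 0.5, 1))))
  sizes <- as.integer(sizes)
  if (length(sizes) < 2L) stop("need at least 2 subsample sizes")
  if (is.unsorted(sizes, strictly = TRUE))
    stop("sizes must be strictly increasing")
  if (max(sizes) > m) stop("max(sizes) must be at most nrow(X)")
  if (k >= min(sizes)) stop("k must be smaller than min(sizes)")
  if (is.null(DMax)) DMax <- ncol(X)
  params <- list(k = k, gamma = gamma, sizes = sizes, nBoot = nBoot,
                 seed = seed)
  meanLogL <- withSeed(seed, vapply(sizes, function(nq) {
    logL <- vapply(seq_len(nBoot), function(b) {
      sel <- if (nq == m) seq_len(m) else sort(sample.int(m, nq))
      nt <- buildNeighborTable(X[sel, , drop = FALSE], k)
      log(sum(nt@distances^gamma))
    }, numeric(1))
    mean(logL)
  }, numeric(1)))
  fitLm <- lm(meanLogL ~ log(sizes))
  a <- unname(coef(fitLm)[2L])
  params$slope <- a
  if (!is.finite(a) || a >= 1)
    return(newIDEstimate("KNN", NA_real_, params, max(sizes),
                         degenerate = FALSE))
  d <- min(max(round(gamma / (1 - a)), 1), DMax)
  newIDEstimate("KNN", as.numeric(d), params, max(sizes))
}
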
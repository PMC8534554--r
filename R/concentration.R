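## Probability that two independent uniform unit vectors in n dimensions
## have inner product above alpha (spherical-cap probability, exact
## regularized incomplete-beta form). Strictly decreasing in n, which
## makes the inversion below unique.
.insepProb <- function(alpha, n) {
  0.5 * pbeta(1 - alpha^2, (n - 1) / 2, 0.5)
}

## Invert p(alpha, n) in n by bracketed root finding on the log scale.
.insepInvert <- function(pbar, alpha, nMax = 1e6) {
  lo <- 1 + 1e-9
  if (pbar >= .insepProb(alpha, lo)) return(1)
  ## grow the upper bracket geometrically so the log never underflows
  hi <- 2
  while (hi < nMax && .insepProb(alpha, hi) > pbar) hi <- hi * 2
  if (.insepProb(alpha, hi) > pbar) return(nMax)
  uniroot(function(n) log(.insepProb(alpha, n)) - log(pbar),
          c(lo, hi), tol = 1e-10)$root
}

#' Fisher-separability dimension estimator
#'
#' Exploits the concentration-of-measure fact that in high dimension
#' almost every point of a uniform cloud is linearly (Fisher-) separable
#' from the rest. The data are centered, whitened on the well-conditioned
#' principal components (eigenvalues within `condRatio` of the top one),
#' and projected to the unit sphere. A point `x` is alpha-inseparable
#' from `y` when the inner product of their unit vectors exceeds `alpha`;
#' the observed mean inseparability fraction `pbar(alpha)` is matched to
#' its exact value for uniform unit vectors in `n` dimensions (a
#' spherical-cap probability, decaying geometrically in `n`), and the
#' dimension is the continuous `n` solving that equation, found by
#' bracketed root finding.
#'
#' @param X Numeric matrix, at least 10 rows.
#' @param alphas Grid of thresholds in (0,1), strictly increasing.
#' @param condRatio Condition-number cap for component retention
#'   (default 10): components with `lambda_1/lambda_i >= condRatio` are
#'   dropped before whitening.
#' @param alphaSelect `"fixed"` (use `alphaFixed`, the default) or
#'   `"auto"` (the grid alpha closest to the center of the range where
#'   `pbar` is strictly inside (0,1)).
#' @param alphaFixed Threshold used when `alphaSelect = "fixed"`
#'   (default 0.8).
#' @return An [IDEstimate-class] tagged `"FisherS"`, with the selected
#'   alpha, the observed `pbar` and the number of dropped zero-norm
#'   points in `params`. If every point is separable at every alpha
#'   (`pbar = 0`) the status is `"invalid_infinite"`.
#' @examples
#' X <- samplePoints(generateManifold("hyperball", 1000, list(d = 5),
#'                                    seed = 1))
#' idValue(fisherS(X))
#' @export
fisherS <- function(X, alphas = seq(0.6, 0.98, by = 0.02),
                    condRatio = 10, alphaSelect = c("fixed", "auto"),
                    alphaFixed = 0.8) {
  alphaSelect <- match.arg(alphaSelect)
  X <- asDataMatrix(X)
  stopifnot(all(alphas > 0), all(alphas < 1),
            !is.unsorted(alphas, strictly = TRUE))
  if (nrow(X) < 10L) stop("FisherS needs at least 10 rows")
  m0 <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X), "-")
  eg <- eigen(crossprod(Xc) / (m0 - 1), symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  keep <- lam > 0 & lam[1] / pmax(lam, .Machine$double.xmin) < condRatio
  if (!any(keep)) keep[1] <- lam[1] > 0
  if (!any(keep)) stop("degenerate input: zero covariance")
  Y <- Xc %*% eg$vectors[, keep, drop = FALSE]
  Y <- sweep(Y, 2L, sqrt(lam[keep]), "/")          # whiten
  nrm <- sqrt(rowSums(Y^2))
  dropped <- sum(nrm == 0)
  U <- Y[nrm > 0, , drop = FALSE] / nrm[nrm > 0]   # unit sphere
  m <- nrow(U)
  G <- tcrossprod(U)
  pbar <- vapply(alphas, function(a)
    mean((rowSums(G > a) - 1) / (m - 1)), numeric(1))
  alpha <- if (alphaSelect == "fixed") alphaFixed else {
    usable <- which(pbar > 0 & pbar < 1)
    if (!length(usable)) alphaFixed else {
      ctr <- (alphas[usable[1]] + alphas[usable[length(usable)]]) / 2
      alphas[usable[which.min(abs(alphas[usable] - ctr))]]
    }
  }
  pa <- if (alpha %in% alphas) pbar[match(alpha, alphas)] else
    mean((rowSums(G > alpha) - 1) / (m - 1))
  params <- list(alpha = alpha, pbar = pa, condRatio = condRatio,
                 droppedZeroNorm = dropped, pbarGrid = setNames(pbar,
                 alphas))
  if (pa <= 0)
    return(new("IDEstimate", method = "FisherS", value = NA_real_,
               status = "invalid_infinite", params = params,
               nUsed = as.integer(m)))
  newIDEstimate("FisherS", .insepInvert(pa, alpha), params, m)
}

#' Expected-simplex-skewness theoretical curve
#'
#' The expected absolute sine `T(n) = E|sin theta|` of the angle between
#' two independent uniform directions in `n` dimensions, computed as the
#' ratio of Wallis integrals
#' `int_0^pi sin^(n-1) / int_0^pi sin^(n-2)` in closed gamma-function
#' form. `T` is strictly increasing in `n` with `T(1) = 0`,
#' `T(2) = 2/pi` and `T(3) = pi/4`, which makes its inverse unique.
#'
#' @param n Dimension(s), `n >= 1` (vectorized).
#' @return `T(n)` as a numeric vector.
#' @examples
#' essCurve(2:3)  # 2/pi, pi/4
#' @export
essCurve <- function(n) {
  vapply(n, function(nn) {
    if (nn < 1) stop("n must be >= 1")
    if (nn == 1) return(0)
    ## Wallis: int_0^pi sin^m = sqrt(pi) * G((m+1)/2) / G(m/2 + 1)
    exp((lgamma(nn / 2) - lgamma((nn + 1) / 2)) -
        (lgamma((nn - 1) / 2) - lgamma(nn / 2)))
  }, numeric(1))
}

#' Invert the expected-simplex-skewness curve
#'
#' Piecewise-linear inverse of [essCurve()] over integer knots
#' `1..pMax`: returns the continuous dimension whose expected
#' `|sin theta|` equals the observed statistic, clamped to `[1, pMax]`.
#'
#' @param s Observed mean absolute sine in `[0, 1)`.
#' @param pMax Upper clamp (ambient dimension).
#' @return Continuous dimension estimate.
#' @examples
#' essInvertCurve(2 / pi, 10)  # exactly 2
#' @export
essInvertCurve <- function(s, pMax) {
  pMax <- max(1L, as.integer(pMax))
  knots <- essCurve(seq_len(pMax))
  hit <- which(abs(knots - s) <= 4 * .Machine$double.eps)
  if (length(hit)) return(as.numeric(hit[1L]))  # exact at the knots
  if (s <= knots[1]) return(1)
  if (s >= knots[pMax]) return(as.numeric(pMax))
  i <- findInterval(s, knots)
  i + (s - knots[i]) / (knots[i + 1] - knots[i])
}

#' Expected-simplex-skewness dimension estimator
#'
#' Measures the mean absolute sine of the angle between pairs of vectors
#' from the cloud centroid to its points. In higher dimension random
#' directions are closer to orthogonal, so the statistic increases with
#' dimension; the estimate is the (continuous) dimension whose
#' theoretical curve [essCurve()] matches the observation, by
#' piecewise-linear inversion. This is the pair/angle (simplex order 1)
#' version of the simplex-skewness family. The estimator is quadratic in
#' the number of points, so inputs beyond the `maxRows` x `maxCols` cap
#' are refused unless `force = TRUE` (reduce first, e.g. with
#' [applyMethodCaps()]).
#'
#' @param X Numeric matrix, at least 3 rows.
#' @param nPairs Maximum number of vector pairs used; when the total
#'   number of pairs exceeds it, `nPairs` pairs are sampled with `seed`.
#' @param seed Integer seed for pair sampling.
#' @param maxRows,maxCols Cost-guard caps (defaults 2000 and 20).
#' @param force Bypass the cost guard?
#' @return An [IDEstimate-class] tagged `"ESS"`.
#' @examples
#' X <- samplePoints(generateManifold("hyperball", 500, list(d = 3),
#'                                    seed = 1))
#' idValue(essID(X))
#' @export
essID <- function(X, nPairs = 1e5, seed = 0L, maxRows = 2000L,
                  maxCols = 20L, force = FALSE) {
  X <- asDataMatrix(X)
  if (!force && (nrow(X) > maxRows || ncol(X) > maxCols))
    stop("ESS input exceeds its ", maxRows, " x ", maxCols,
         " cost cap; reduce it (see applyMethodCaps) or use force = TRUE")
  if (nrow(X) < 3L) stop("ESS needs at least 3 rows")
  V <- sweep(X, 2L, colMeans(X), "-")
  nrm <- sqrt(rowSums(V^2))
  V <- V[nrm > 0, , drop = FALSE] / nrm[nrm > 0]
  m <- nrow(V)
  params <- list(nPairs = nPairs, dSimplex = 1L)
  if (m < 2L)
    return(newIDEstimate("ESS", NA_real_, params, m, degenerate = TRUE))
  total <- m * (m - 1) / 2
  if (total <= nPairs) {
    cosv <- tcrossprod(V)[upper.tri(diag(m))]
  } else {
    ij <- withSeed(seed, {
      i <- sample.int(m, nPairs, replace = TRUE)
      j <- sample.int(m - 1L, nPairs, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)
      cbind(i, j)
    })
    cosv <- rowSums(V[ij[, 1L], , drop = FALSE] *
                    V[ij[, 2L], , drop = FALSE])
  }
  cosv <- pmin(pmax(cosv, -1), 1)
  s <- mean(sqrt(1 - cosv^2))
  params$statistic <- s
  newIDEstimate("ESS", essInvertCurve(s, ncol(X)), params, m)
}

## --- DANCo -----------------------------------------------------------

## von Mises ML fit of a sample of angles: mean direction nu and
## concentration tau (Best-Fisher approximation to A^{-1}(R)).
.fitVonMises <- function(theta) {
  C <- mean(cos(theta)); S <- mean(sin(theta))
  R <- sqrt(C^2 + S^2)
  nu <- atan2(S, C)
  tau <- if (R < 0.53) 2 * R + R^3 + 5 * R^5 / 6
         else if (R < 0.85) -0.4 + 1.39 * R + 0.43 / (1 - R)
         else 1 / (R^3 - 4 * R^2 + 3 * R)
  c(nu = nu, tau = min(tau, 1e5))
}

## log I0 via the exponentially scaled Bessel function (stable for large
## tau).
.logI0 <- function(tau) log(besselI(tau, 0, expon.scaled = TRUE)) + tau
.besselRatio <- function(tau)
  besselI(tau, 1, expon.scaled = TRUE) / besselI(tau, 0,
                                                 expon.scaled = TRUE)

## KL divergence between two von Mises distributions (closed form).
.klVonMises <- function(nu1, tau1, nu2, tau2) {
  .logI0(tau2) - .logI0(tau1) +
    .besselRatio(tau1) * (tau1 - tau2 * cos(nu1 - nu2))
}

## KL divergence between the normalized-distance densities
## g(rho; d, k) = k d rho^(d-1) (1 - rho^d)^(k-1), by numerical
## integration on (0, 1).
.klMindDensity <- function(d1, d2, k) {
  lg <- function(rho, d)
    log(k * d) + (d - 1) * log(rho) + (k - 1) * log1p(-rho^d)
  f <- function(rho) {
    v <- exp(lg(rho, d1)) * (lg(rho, d1) - lg(rho, d2))
    v[!is.finite(v)] <- 0
    v
  }
  integrate(f, 0, 1, rel.tol = 1e-8, stop.on.error = FALSE)$value
}

## Norm and angle statistics used by DANCo: continuous ML dimension from
## rho = r1/rk, and a von Mises (location, concentration) fit of the
## pairwise angles between the vectors from each point to its neighbors,
## summarized over points by the circular mean of locations and the mean
## concentration.
.dancoStats <- function(X, k) {
  nt <- buildNeighborTable(X, k)
  D <- nt@distances
  rho <- D[, 1L] / D[, k]
  rho <- rho[is.finite(rho) & rho > 0 & rho < 1]
  if (!length(rho)) return(NULL)
  dML <- optimize(.mindLogLik, c(1e-2, ncol(X) + 1), rho = rho, k = k,
                  maximum = TRUE, tol = 1e-8)$maximum
  m <- nrow(X)
  ut <- upper.tri(diag(k))
  fits <- matrix(NA_real_, m, 2L)
  for (i in seq_len(m)) {
    A <- X[nt@indices[i, ], , drop = FALSE] -
      matrix(X[i, ], k, ncol(X), byrow = TRUE)
    nr <- sqrt(rowSums(A^2))
    if (any(nr == 0)) next
    A <- A / nr
    cosv <- pmin(pmax(tcrossprod(A)[ut], -1), 1)
    fits[i, ] <- .fitVonMises(acos(cosv))
  }
  fits <- fits[is.finite(fits[, 1L]), , drop = FALSE]
  if (!nrow(fits)) return(NULL)
  list(d = dML,
       nu = atan2(mean(sin(fits[, 1L])), mean(cos(fits[, 1L]))),
       tau = mean(fits[, 2L]))
}

.dancoCache <- new.env(parent = emptyenv())

#' Angle-and-norm concentration (DANCo) dimension estimator
#'
#' Jointly compares two concentration statistics of the data with the
#' same statistics measured on calibration samples of known dimension:
#' (a) the maximum-likelihood dimension of the normalized closest-neighbor
#' distance `rho = r_1/r_k`, and (b) a von Mises location--concentration
#' fit of the pairwise angles between the vectors from each point to its
#' k neighbors. For every candidate dimension `d` in `1..DMax`, `nCalib`
#' points are drawn uniformly on the d-sphere (seeded, cached per
#' `(d, k, nCalib, seed)`), and the estimate is the candidate minimizing
#' the sum of two Kullback--Leibler terms: between the fitted
#' normalized-distance densities and between the fitted von Mises angle
#' distributions. Calibration sizes default to desk-scale runtime rather
#' than maximal fidelity; increase `nCalib` for sharper calibration. The
#' quadratic/cubic cost is guarded by a `maxRows` x `maxCols` cap,
#' bypassable with `force = TRUE`.
#'
#' @param X Numeric matrix, `nrow(X) >= k + 2`.
#' @param k Number of neighbors (default 10).
#' @param DMax Candidate-dimension cap, default ambient dimension.
#' @param nCalib Calibration points per candidate dimension
#'   (default 100; must exceed `k`).
#' @param seed Integer seed for the calibration samples.
#' @param maxRows,maxCols Cost-guard caps (defaults 10000 and 100).
#' @param force Bypass the cost guard?
#' @return An [IDEstimate-class] tagged `"DANCo"`; the value is an
#'   integer in `[1, DMax]`, with the per-candidate KL profile in
#'   `params$kl`.
#' @examples
#' X <- samplePoints(generateManifold("hypersphere", 500, list(d = 2),
#'                                    seed = 1))
#' idValue(danco(X, seed = 1))
#' @export
danco <- function(X, k = 10L, DMax = NULL, nCalib = 100L, seed = 0L,
                  maxRows = 10000L, maxCols = 100L, force = FALSE) {
  X <- asDataMatrix(X)
  k <- as.integer(k); nCalib <- as.integer(nCalib)
  if (!force && (nrow(X) > maxRows || ncol(X) > maxCols))
    stop("DANCo input exceeds its ", maxRows, " x ", maxCols,
         " cost cap; reduce it (see applyMethodCaps) or use force = TRUE")
  if (nrow(X) < k + 2L) stop("DANCo needs at least k + 2 rows")
  stopifnot(2L <= k, k < nCalib)
  if (is.null(DMax)) DMax <- ncol(X)
  DMax <- max(1L, as.integer(DMax))
  params <- list(k = k, DMax = DMax, nCalib = nCalib, seed = seed)
  obs <- .dancoStats(X, k)
  if (is.null(obs))
    return(newIDEstimate("DANCo", NA_real_, params, nrow(X),
                         degenerate = TRUE))
  kl <- rep(NA_real_, DMax)
  for (d in seq_len(DMax)) {
    key <- paste(d, k, nCalib, seed, sep = "_")
    cal <- .dancoCache[[key]]
    if (is.null(cal)) {
      cal <- withSeed(seed + d, {
        S <- .sampleSphere(nCalib, d)
        .dancoStats(S, k)
      })
      if (!is.null(cal)) .dancoCache[[key]] <- cal
    }
    if (is.null(cal)) next  # calibration failure: candidate skipped
    kl[d] <- .klMindDensity(obs$d, cal$d, k) +
      .klVonMises(obs$nu, obs$tau, cal$nu, cal$tau)
  }
  params$kl <- kl
  if (all(is.na(kl)))
    return(newIDEstimate("DANCo", NA_real_, params, nrow(X),
                         degenerate = TRUE))
  newIDEstimate("DANCo", as.numeric(which.min(kl)), params, nrow(X))
}
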
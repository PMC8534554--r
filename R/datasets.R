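## Uniform sample on the surface of the d-sphere embedded in R^(d+1).
.sampleSphere <- function(n, d) {
  Z <- matrix(rnorm(n * (d + 1L)), n, d + 1L)
  Z / sqrt(rowSums(Z^2))
}

## Uniform sample in the d-ball of given radius (polar method).
.sampleBall <- function(n, d, radius = 1) {
  Z <- matrix(rnorm(n * d), n, d)
  dirs <- Z / sqrt(rowSums(Z^2))
  radius * runif(n)^(1 / d) * dirs
}

## Registry of manifold generators. Each entry: function(n, params) run
## inside a seeded RNG scope, returning list(points, intrinsicDim).
## Latent samples are uniform on the stated support; nonlinear entries
## push a low-dimensional latent sample through a smooth injective map,
## which preserves the intrinsic dimension.
.MANIFOLDS <- list(
  hyperball = function(n, p) {
    d <- p$d %||% 2L
    list(points = .sampleBall(n, d, p$radius %||% 1), intrinsicDim = d)
  },
  hypersphere = function(n, p) {
    d <- p$d %||% 2L
    list(points = .sampleSphere(n, d), intrinsicDim = d)
  },
  gaussian = function(n, p) {
    d <- p$d %||% 2L
    sigma <- p$sigma %||% 1
    list(points = matrix(rnorm(n * d, sd = sigma), n, d), intrinsicDim = d)
  },
  hypercube = function(n, p) {
    d <- p$d %||% 2L
    list(points = matrix(runif(n * d), n, d), intrinsicDim = d)
  },
  swiss_roll = function(n, p) {
    t <- runif(n, 1.5 * pi, 4.5 * pi)
    y <- runif(n, 0, 21)
    list(points = cbind(t * cos(t), y, t * sin(t)), intrinsicDim = 2L)
  },
  moebius = function(n, p) {
    u <- runif(n, 0, 2 * pi)
    v <- runif(n, -1, 1)
    w <- 1 + (v / 2) * cos(u / 2)
    list(points = cbind(w * cos(u), w * sin(u), (v / 2) * sin(u / 2)),
         intrinsicDim = 2L)
  },
  helix = function(n, p) {
    t <- runif(n, 0, 4 * pi)
    list(points = cbind(cos(t), sin(t), 0.5 * t), intrinsicDim = 1L)
  },
  nonlinear_sphere_embedding = function(n, p) {
    d <- p$d %||% 2L
    D <- p$D %||% (2L * d + 2L)
    if (d + 1L > D)
      stop("embedding requires D >= d + 1")
    W <- matrix(rnorm(D * (d + 1L), sd = 1 / sqrt(d + 1)), D, d + 1L)
    Z <- .sampleSphere(n, d)
    ## tanh after an injective linear map is injective: dim preserved
    list(points = tanh(Z %*% t(W)), intrinsicDim = d)
  },
  affine_subspace = function(n, p) {
    d <- p$d %||% 2L
    D <- p$D %||% (2L * d)
    if (d > D) stop("embedding requires d <= D")
    B <- qr.Q(qr(matrix(rnorm(D * d), D, d)))  # orthonormal basis
    Z <- matrix(rnorm(n * d), n, d)
    if (isTRUE(p$isotropic)) {
      ## exact whitening: latent sample covariance becomes the identity,
      ## so the embedded spectrum is exactly d equal nonzero eigenvalues
      Z <- sweep(Z, 2L, colMeans(Z), "-")
      Z <- Z %*% solve(chol(crossprod(Z) / (n - 1)))
    }
    shift <- rnorm(D)
    list(points = sweep(Z %*% t(B), 2L, shift, "+"), intrinsicDim = d)
  }
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a benchmark manifold sample
#'
#' Draws `n` points uniformly from a registered synthetic manifold of
#' known intrinsic dimension. These samples are the standard fixtures for
#' validating ID estimators: the true dimension is known by construction.
#' Output is byte-identical for identical `(name, n, params, seed)`.
#'
#' Registered names and their parameters:
#' \describe{
#'   \item{`hyperball(d, radius)`}{uniform in the d-ball (ambient d).}
#'   \item{`hypersphere(d)`}{uniform on the d-sphere surface (ambient d+1).}
#'   \item{`gaussian(d, sigma)`}{isotropic Gaussian in d dimensions.}
#'   \item{`hypercube(d)`}{uniform in the unit d-cube.}
#'   \item{`swiss_roll`}{the classic 2-D roll in 3-D.}
#'   \item{`moebius`}{Moebius band in 3-D (intrinsic 2).}
#'   \item{`helix`}{a 1-D helical curve in 3-D.}
#'   \item{`nonlinear_sphere_embedding(d, D)`}{d-sphere pushed through a
#'     seeded random linear map into D dimensions followed by `tanh`
#'     (smooth and injective, so intrinsic dimension d is preserved).}
#'   \item{`affine_subspace(d, D, isotropic)`}{Gaussian d-dimensional
#'     latent cloud in a random orthonormal d-frame of R^D (exactly rank
#'     d); `isotropic = TRUE` whitens the latent sample exactly so the d
#'     nonzero eigenvalues are equal.}
#'   \item{`line_disk_ball`}{see [lineDiskBall()].}
#' }
#' The registry is deliberately extensible: further benchmark maps can be
#' added mechanically as new entries.
#'
#' @param name Registry name (see Details).
#' @param n Number of points (for `line_disk_ball`, points per segment).
#' @param params Named list of manifold parameters.
#' @param seed Integer seed.
#' @param noise Standard deviation of optional isotropic Gaussian ambient
#'   noise added to the points (default 0, i.e. off).
#' @return A [ManifoldSample-class].
#' @examples
#' s <- generateManifold("hypersphere", 500, list(d = 2), seed = 1)
#' range(sqrt(rowSums(samplePoints(s)^2)))  # all norms 1
#' @export
generateManifold <- function(name, n, params = list(), seed = 0L,
                             noise = 0) {
  if (identical(name, "line_disk_ball")) {
    nper <- if (length(n) == 3L) n else rep(n, 3L)
    return(lineDiskBall(nper, seed = seed, noise = noise))
  }
  gen <- .MANIFOLDS[[name]]
  if (is.null(gen))
    stop("unknown manifold '", name, "'; see ?generateManifold")
  n <- as.integer(n)
  if (n < 1L) stop("n must be positive")
  out <- withSeed(seed, {
    res <- gen(n, params)
    if (noise > 0)
      res$points <- res$points +
        matrix(rnorm(length(res$points), sd = noise), nrow(res$points))
    res
  })
  new("ManifoldSample", points = unname(out$points),
      intrinsicDim = as.numeric(out$intrinsicDim),
      ambientDim = ncol(out$points), labels = character(0),
      seed = as.integer(seed), name = name)
}

#' The line--disk--ball benchmark
#'
#' Concatenates a 1-D segment, a 2-D disk and a 3-D ball at fixed disjoint
#' offsets in 3-D ambient space, with per-point segment labels. The three
#' segments have local intrinsic dimension 1, 2 and 3, so a local
#' estimator should separate them; the offsets are large relative to the
#' segment sizes so that k-nearest-neighbor neighborhoods at default sizes
#' never mix segments.
#'
#' @param nPerSegment Integer triple: points in the line, disk and ball.
#' @param seed Integer seed.
#' @param noise Standard deviation of optional ambient Gaussian noise.
#' @return A [ManifoldSample-class] with labels `"line"`, `"disk"`,
#'   `"ball"` and per-segment intrinsic dimensions `c(1, 2, 3)`.
#' @examples
#' table(segmentLabels(lineDiskBall(c(100, 100, 100), seed = 0)))
#' @export
lineDiskBall <- function(nPerSegment, seed = 0L, noise = 0) {
  stopifnot(length(nPerSegment) == 3L, all(nPerSegment >= 1L))
  nPerSegment <- as.integer(nPerSegment)
  pts <- withSeed(seed, {
    line <- cbind(runif(nPerSegment[1L]), 0, 0)
    th <- runif(nPerSegment[2L], 0, 2 * pi)
    rr <- 0.5 * sqrt(runif(nPerSegment[2L]))
    disk <- cbind(3 + rr * cos(th), rr * sin(th), 0)
    ball <- sweep(.sampleBall(nPerSegment[3L], 3L, 0.5), 2L,
                  c(6, 0, 0), "+")
    P <- rbind(line, disk, ball)
    if (noise > 0)
      P <- P + matrix(rnorm(length(P), sd = noise), nrow(P))
    P
  })
  labels <- rep(c("line", "disk", "ball"), nPerSegment)
  new("ManifoldSample", points = unname(pts), intrinsicDim = c(1, 2, 3),
      ambientDim = 3L, labels = labels, seed = as.integer(seed),
      name = "line_disk_ball")
}
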
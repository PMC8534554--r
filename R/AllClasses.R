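#' NeighborTable: exact k-nearest-neighbor indices and distances
#'
#' Per-point sorted k-nearest-neighbor row indices and Euclidean distances,
#' the substrate of all nearest-neighbor distance estimators. Rows of
#' `distances` are non-decreasing; a point is never its own neighbor; ties
#' are broken deterministically by lower row index.
#'
#' @slot k Neighborhood size.
#' @slot indices M x k integer matrix of neighbor row indices (1-based).
#' @slot distances M x k numeric matrix of sorted Euclidean distances.
#'
#' @seealso [buildNeighborTable()]
#' @export
setClass("NeighborTable",
  representation(k = "integer", indices = "matrix", distances = "matrix"),
  validity = function(object) {
    msg <- character()
    if (object@k < 1L) msg <- c(msg, "k must be positive")
    if (!identical(dim(object@indices), dim(object@distances)))
      msg <- c(msg, "indices and distances must have identical shape")
    if (ncol(object@indices) != object@k)
      msg <- c(msg, "matrices must have k columns")
    if (any(object@distances < 0)) msg <- c(msg, "distances must be >= 0")
    if (nrow(object@distances) > 0 && ncol(object@distances) > 1 &&
        any(object@distances[, -1, drop = FALSE] <
            object@distances[, -ncol(object@distances), drop = FALSE]))
      msg <- c(msg, "each distance row must be non-decreasing")
    if (any(object@indices == seq_len(nrow(object@indices))))
      msg <- c(msg, "a point must not be its own neighbor")
    if (length(msg)) msg else TRUE
  })

#' EigenSpectrum: non-increasing covariance eigenvalues
#'
#' The eigenvalues of a sample covariance matrix, sorted non-increasing,
#' with values below a relative tolerance clamped to zero. The substrate of
#' every PCA dimension criterion.
#'
#' @slot lambdas Non-negative numeric vector, sorted non-increasing.
#' @seealso [covarianceSpectrum()], [pcaDimension()]
#' @export
setClass("EigenSpectrum",
  representation(lambdas = "numeric"),
  validity = function(object) {
    l <- object@lambdas
    if (length(l) < 1L) return("spectrum must be non-empty")
    if (any(l < 0)) return("eigenvalues must be non-negative")
    if (is.unsorted(rev(l))) return("eigenvalues must be non-increasing")
    TRUE
  })

#' IDEstimate: a global intrinsic-dimension estimate with validity status
#'
#' The result of a global estimator: a method tag, a numeric value (NA when
#' the method could not produce one), a status code, the parameters used,
#' and the number of observations actually used after any cap or
#' subsampling. Status is `"ok"` exactly when the value is finite and
#' positive; failures never surface as bare NaN or infinities.
#'
#' @slot method Method tag (e.g. `"MLE"`, `"lPCA_FO"`).
#' @slot value Numeric estimate, or `NA_real_` when invalid.
#' @slot status One of `"ok"`, `"invalid_nan"`, `"invalid_negative"`,
#'   `"invalid_infinite"`, `"degenerate_input"`.
#' @slot params Named list of parameters the estimator ran with.
#' @slot nUsed Number of rows used.
#' @seealso [estimateGlobal()]
#' @export
setClass("IDEstimate",
  representation(method = "character", value = "numeric",
                 status = "character", params = "list", nUsed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@status %in% .ID_STATUSES)
      msg <- c(msg, "unknown status code")
    okval <- length(object@value) == 1L && is.finite(object@value) &&
      object@value > 0
    if (identical(object@status, "ok") != okval)
      msg <- c(msg, "status 'ok' must coincide with a finite positive value")
    if (length(msg)) msg else TRUE
  })

#' LocalIDField: per-point local intrinsic-dimension estimates
#'
#' One value per observation, obtained by applying a global estimator to
#' the sub-cloud of each point and its k nearest neighbors. Invalid
#' per-point results carry a status code and an `NA` value.
#'
#' @slot values Numeric vector of length M (NA where invalid).
#' @slot statuses Character vector of per-point status codes.
#' @slot k Neighborhood size used.
#' @slot method Global method tag that was applied locally.
#' @seealso [estimateLocal()]
#' @export
setClass("LocalIDField",
  representation(values = "numeric", statuses = "character",
                 k = "integer", method = "character"),
  validity = function(object) {
    if (length(object@values) != length(object@statuses))
      return("values and statuses must have equal length")
    if (!all(object@statuses %in% .ID_STATUSES))
      return("unknown status code")
    TRUE
  })

#' ManifoldSample: a seeded sample from a benchmark manifold
#'
#' Points sampled uniformly from a registered synthetic manifold of known
#' intrinsic dimension, with optional per-point segment labels (used by the
#' line--disk--ball benchmark, whose segments have different local ID).
#'
#' @slot points Numeric M x p matrix of sampled coordinates.
#' @slot intrinsicDim Intrinsic dimension(s); one value, or one per segment.
#' @slot ambientDim Number of ambient coordinates (equals `ncol(points)`).
#' @slot labels Per-point segment tags, or `character(0)` when unlabeled.
#' @slot seed Seed the sample was drawn with.
#' @slot name Registry name of the manifold.
#' @seealso [generateManifold()], [lineDiskBall()]
#' @export
setClass("ManifoldSample",
  representation(points = "matrix", intrinsicDim = "numeric",
                 ambientDim = "integer", labels = "character",
                 seed = "integer", name = "character"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@points) != object@ambientDim)
      msg <- c(msg, "ambientDim must equal ncol(points)")
    if (length(object@labels) &&
        length(object@labels) != nrow(object@points))
      msg <- c(msg, "labels must have one entry per point")
    if (length(msg)) msg else TRUE
  })

#' ProfileMatrix: intrinsic-dimension profiles for a dataset collection
#'
#' A datasets-by-methods table of ID estimates with a parallel status
#' matrix; a cell is missing (NA) exactly when its status is not `"ok"`.
#' The input of the consensus, correlation and imputation layers.
#'
#' @slot values Numeric datasets x methods matrix (NA marks missing).
#' @slot statuses Character matrix of the same shape.
#' @slot nUsed Integer matrix of the same shape: rows actually used per
#'   cell after caps/subsampling (NA where unknown).
#' @seealso [runProfile()], [consensusID()], [imputeProfile()]
#' @export
setClass("ProfileMatrix",
  representation(values = "matrix", statuses = "matrix",
                 nUsed = "matrix"),
  prototype(nUsed = matrix(NA_integer_, 0, 0)),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@values), dim(object@statuses)))
      msg <- c(msg, "values and statuses must have identical shape")
    else {
      miss <- is.na(object@values)
      bad <- miss != (object@statuses != "ok")
      if (any(bad)) msg <- c(msg, "missing cells must match non-ok statuses")
    }
    if (length(object@nUsed) &&
        !identical(dim(object@values), dim(object@nUsed)))
      msg <- c(msg, "nUsed must match the shape of values (or be empty)")
    if (length(msg)) msg else TRUE
  })

#' ConsensusResult: consensus dimension scores and profile PCA
#'
#' Column z-scores of a complete profile matrix, the per-dataset mean
#' z-score (the consensus ID score, negative for lower-dimensional and
#' positive for higher-dimensional datasets), and a PCA of the z-scored
#' profiles (explained-variance fractions and method loadings).
#'
#' @slot zscores Datasets x methods matrix of column z-scores.
#' @slot meanZ Per-dataset mean z-score.
#' @slot explainedVariance Fraction of variance per principal component.
#' @slot loadings Methods x components loading matrix.
#' @seealso [consensusID()]
#' @export
setClass("ConsensusResult",
  representation(zscores = "matrix", meanZ = "numeric",
                 explainedVariance = "numeric", loadings = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@meanZ) != nrow(object@zscores))
      msg <- c(msg, "meanZ must have one entry per dataset")
    if (abs(sum(object@explainedVariance) - 1) > 1e-9)
      msg <- c(msg, "explained variance fractions must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' TimeModelFit: multiplicative runtime model fit
#'
#' Fit of the model `Time = c * Nobj^alpha * Nvar^beta` by ordinary least
#' squares in log space.
#'
#' @slot c Multiplicative constant (> 0).
#' @slot alpha Exponent of the number of observations.
#' @slot beta Exponent of the number of features.
#' @slot rSquared Coefficient of determination of the log-linear fit.
#' @seealso [fitTimeModel()]
#' @export
setClass("TimeModelFit",
  representation(c = "numeric", alpha = "numeric", beta = "numeric",
                 rSquared = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@c <= 0) msg <- c(msg, "c must be positive")
    if (object@rSquared > 1 + 1e-12) msg <- c(msg, "rSquared must be <= 1")
    if (length(msg)) msg else TRUE
  })

#' SensitivityResult: redundancy sensitivity of one method on one dataset
#'
#' The ratio between the ID estimated on the column-duplicated matrix
#' `[X X]` and the ID estimated on `X`; the ratio is NA unless both runs
#' are valid.
#'
#' @slot method Method tag.
#' @slot idOriginal Estimate on the original matrix (NA if invalid).
#' @slot idDuplicated Estimate on the duplicated matrix (NA if invalid).
#' @slot ratio `idDuplicated / idOriginal`, or NA.
#' @slot statusOriginal,statusDuplicated Status codes of the two runs.
#' @seealso [redundancySensitivity()]
#' @export
setClass("SensitivityResult",
  representation(method = "character", idOriginal = "numeric",
                 idDuplicated = "numeric", ratio = "numeric",
                 statusOriginal = "character",
                 statusDuplicated = "character"))
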
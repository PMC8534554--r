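## Registry of the 19 global estimators. Each entry is
## function(X, params, seed, clamp): clamp = TRUE shrinks
## neighborhood-type parameters to fit small sub-clouds (used by
## estimateLocal).
.pcaEntry <- function(variant) {
  function(X, params, seed, clamp) {
    def <- list(alphaFO = 0.05, fanRatioR = 10, fanCumC = 0.8,
                ratioTau = 0.95, round = FALSE)
    pp <- mergeParams(def, params)
    est <- pcaDimension(covarianceSpectrum(X), variant,
                        alphaFO = pp$alphaFO, fanRatioR = pp$fanRatioR,
                        fanCumC = pp$fanCumC, ratioTau = pp$ratioTau,
                        round = pp$round)
    est@nUsed <- nrow(X)
    est
  }
}

## Neighborhood clamp for local (sub-cloud) use: Hill/ratio estimators
## need the k-th neighbor distance inside the bulk of the sample, so on a
## sub-cloud the wrapped method's k shrinks to at most floor(n/2).
.clampK <- function(k, n, kmin = 2L) max(kmin, min(k, n %/% 2L))

.METHODS <- list(
  lPCA_FO     = .pcaEntry("FO"),
  lPCA_Fan    = .pcaEntry("Fan"),
  lPCA_maxgap = .pcaEntry("maxgap"),
  lPCA_ratio  = .pcaEntry("ratio"),
  lPCA_PR     = .pcaEntry("participation_ratio"),
  lPCA_Kaiser = .pcaEntry("Kaiser"),
  lPCA_BS     = .pcaEntry("broken_stick"),
  CorrInt = function(X, params, seed, clamp) {
    pp <- mergeParams(list(k1 = 10L, k2 = 20L), params)
    if (clamp) {
      pp$k2 <- .clampK(pp$k2, nrow(X), 3L)
      pp$k1 <- min(pp$k1, pp$k2 - 1L)
    }
    corrInt(X, pp$k1, pp$k2)
  },
  MLE = function(X, params, seed, clamp) {
    pp <- mergeParams(list(k = 20L, aggregate = "global_mackay"), params)
    if (clamp) pp$k <- .clampK(pp$k, nrow(X))
    mleID(X, pp$k, pp$aggregate)
  },
  TwoNN = function(X, params, seed, clamp) {
    pp <- mergeParams(list(discardFraction = 0.1, fit = "linear"),
                      params)
    twoNN(X, pp$discardFraction, pp$fit)
  },
  MADA = function(X, params, seed, clamp) {
    pp <- mergeParams(list(k = 20L, aggregate = "mean"), params)
    if (clamp) pp$k <- .clampK(pp$k, nrow(X))
    mada(X, pp$k, pp$aggregate)
  },
  MOM = function(X, params, seed, clamp) {
    pp <- mergeParams(list(k = 20L), params)
    if (clamp) pp$k <- .clampK(pp$k, nrow(X))
    momID(X, pp$k)
  },
  TLE = function(X, params, seed, clamp) {
    pp <- mergeParams(list(k = 20L), params)
    if (clamp) pp$k <- .clampK(pp$k, nrow(X), 3L)
    tleID(X, pp$k)
  },
  MiND_MLi = function(X, params, seed, clamp) {
    pp <- mergeParams(list(k = 10L, DMax = NULL), params)
    if (clamp) pp$k <- .clampK(pp$k, nrow(X))
    mindML(X, pp$k, "MLi", pp$DMax)
  },
  MiND_MLk = function(X, params, seed, clamp) {
    pp <- mergeParams(list(k = 10L, DMax = NULL), params)
    if (clamp) pp$k <- .clampK(pp$k, nrow(X))
    mindML(X, pp$k, "MLk", pp$DMax)
  },
  KNN = function(X, params, seed, clamp) {
    pp <- mergeParams(list(k = 5L, gamma = 1, sizes = NULL,
                           nBoot = 10L, DMax = NULL), params)
    if (clamp) pp$k <- max(1L, min(pp$k, nrow(X) %/% 4L - 1L))
    knnGraphID(X, pp$k, pp$gamma, pp$sizes, pp$nBoot, seed, pp$DMax)
  },
  FisherS = function(X, params, seed, clamp) {
    pp <- mergeParams(list(alphas = seq(0.6, 0.98, by = 0.02),
                           condRatio = 10, alphaSelect = "fixed",
                           alphaFixed = 0.8), params)
    fisherS(X, pp$alphas, pp$condRatio, pp$alphaSelect, pp$alphaFixed)
  },
  ESS = function(X, params, seed, clamp) {
    pp <- mergeParams(list(nPairs = 1e5, maxRows = 2000L,
                           maxCols = 20L, force = FALSE), params)
    essID(X, pp$nPairs, seed, pp$maxRows, pp$maxCols, pp$force)
  },
  DANCo = function(X, params, seed, clamp) {
    pp <- mergeParams(list(k = 10L, DMax = NULL, nCalib = 100L,
                           maxRows = 10000L, maxCols = 100L,
                           force = FALSE), params)
    if (clamp) pp$k <- .clampK(pp$k, nrow(X) - 1L)
    danco(X, pp$k, pp$DMax, pp$nCalib, seed, pp$maxRows, pp$maxCols,
          pp$force)
  }
)

#' List the registered global estimators
#'
#' @return Character vector of the 19 method tags accepted by
#'   [estimateGlobal()], [estimateLocal()] and [runProfile()].
#' @examples
#' listMethods()
#' @export
listMethods <- function() names(.METHODS)

#' Estimate global intrinsic dimension by any registered method
#'
#' Uniform front end to the 19 estimators: dispatches on a method tag,
#' fills in that method's default parameters, and returns a structured
#' estimate carrying a validity status instead of bare NaN/Inf. See
#' [listMethods()] for the tags and the individual estimator pages for
#' parameters and semantics.
#'
#' @param X Numeric matrix (observations x features), or a
#'   [ManifoldSample-class] whose points are used.
#' @param method Method tag, e.g. `"MLE"`, `"lPCA_FO"`, `"TwoNN"`.
#' @param params Named list of parameter overrides for the method.
#' @param seed Integer seed forwarded to stochastic methods (k-NN graph
#'   subsampling, ESS pair sampling, DANCo calibration).
#' @param .clamp Internal: shrink neighborhood parameters to fit small
#'   sub-clouds (used by [estimateLocal()]).
#' @return An [IDEstimate-class].
#' @examples
#' X <- generateManifold("hyperball", 500, list(d = 3), seed = 1)
#' estimateGlobal(X, "MLE")
#' @export
estimateGlobal <- function(X, method, params = list(), seed = 0L,
                           .clamp = FALSE) {
  if (is(X, "ManifoldSample")) X <- X@points
  fn <- .METHODS[[method]]
  if (is.null(fn))
    stop("unknown method '", method, "'; see listMethods()")
  fn(asDataMatrix(X), params, as.integer(seed), isTRUE(.clamp))
}
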
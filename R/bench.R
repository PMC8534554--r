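#' Default per-method input caps
#'
#' Row/column caps applied before estimation when profiling a dataset
#' collection: 100,000 rows for every method, 20,000 rows for the
#' memory-hungry k-NN graph and manifold-adaptive estimators, and
#' 10,000 x 100 / 2000 x 20 for the slow DANCo and ESS estimators.
#'
#' @return Named list: `all` (row cap applied to every dataset) plus
#'   per-method `c(rowCap, colCap)` entries.
#' @examples
#' defaultCaps()
#' @export
defaultCaps <- function() {
  list(all = 100000L,
       KNN = c(20000L, NA_integer_),
       MADA = c(20000L, NA_integer_),
       DANCo = c(10000L, 100L),
       ESS = c(2000L, 20L))
}

#' Reduce a matrix to a row/column cap
#'
#' Applies the profiling reduction used for expensive estimators: the
#' number of features is reduced with PCA-derived coordinates (scores on
#' the leading principal components), and the number of observations by
#' seeded uniform random subsampling.
#'
#' @param X Numeric matrix.
#' @param rowCap Maximum rows (NA = no cap).
#' @param colCap Maximum columns (NA = no cap).
#' @param seed Integer seed for the row subsample.
#' @return A matrix within the caps.
#' @examples
#' dim(applyMethodCaps(matrix(rnorm(3000), 100, 30), 50, 5, seed = 0))
#' @export
applyMethodCaps <- function(X, rowCap = NA, colCap = NA, seed = 0L) {
  X <- asDataMatrix(X)
  if (!is.na(colCap) && ncol(X) > colCap) {
    Xc <- sweep(X, 2L, colMeans(X), "-")
    eg <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
    X <- Xc %*% eg$vectors[, seq_len(colCap), drop = FALSE]
  }
  if (!is.na(rowCap) && nrow(X) > rowCap) {
    sel <- withSeed(seed, sort(sample.int(nrow(X), rowCap)))
    X <- X[sel, , drop = FALSE]
  }
  X
}

#' Profile a collection of datasets across ID estimators
#'
#' Runs a batch of estimators over a collection of data matrices,
#' producing the datasets-by-methods profile matrix that feeds the
#' consensus and correlation layers. Each dataset is preprocessed
#' ([preprocessMatrix()]: min/max scaling, near-duplicate removal, row
#' cap), then reduced per method by [applyMethodCaps()] where a cap
#' binds, and every estimator is run with its default parameters. A
#' failing cell records its status and never aborts the batch; identical
#' seeds give byte-identical output.
#'
#' @param collection Named list of numeric matrices or
#'   [ManifoldSample-class] objects.
#' @param methods Method tags to run (default: all 19).
#' @param caps Cap map as returned by [defaultCaps()].
#' @param seed Integer seed used for subsampling and stochastic methods.
#' @param preprocess Apply [preprocessMatrix()] first? Default TRUE.
#' @return A [ProfileMatrix-class].
#' @examples
#' coll <- list(ball = generateManifold("hyperball", 300, list(d = 3),
#'                                      seed = 1),
#'              cube = generateManifold("hypercube", 300, list(d = 2),
#'                                      seed = 2))
#' pm <- runProfile(coll, c("MLE", "TwoNN", "lPCA_FO"))
#' profileValues(pm)
#' @export
runProfile <- function(collection, methods = listMethods(),
                       caps = defaultCaps(), seed = 0L,
                       preprocess = TRUE) {
  stopifnot(length(collection) >= 1L)
  bad <- setdiff(methods, listMethods())
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "))
  dnames <- names(collection)
  if (is.null(dnames)) dnames <- paste0("dataset", seq_along(collection))
  values <- matrix(NA_real_, length(collection), length(methods),
                   dimnames = list(dnames, methods))
  statuses <- matrix("degenerate_input", length(collection),
                     length(methods), dimnames = list(dnames, methods))
  nUsed <- matrix(NA_integer_, length(collection), length(methods),
                  dimnames = list(dnames, methods))
  for (i in seq_along(collection)) {
    X <- collection[[i]]
    if (is(X, "ManifoldSample")) X <- X@points
    X <- tryCatch({
      if (preprocess)
        preprocessMatrix(X, maxRows = caps$all %||% 100000L, seed = seed)
      else asDataMatrix(X)
    }, error = function(e) NULL)
    if (is.null(X)) next
    for (j in seq_along(methods)) {
      mth <- methods[j]
      cap <- caps[[mth]]
      Xm <- if (is.null(cap)) X else
        applyMethodCaps(X, cap[1L], cap[2L], seed)
      est <- tryCatch(estimateGlobal(Xm, mth, seed = seed),
                      error = function(e)
                        newIDEstimate(mth, NA_real_, degenerate = TRUE))
      statuses[i, j] <- est@status
      nUsed[i, j] <- if (is.na(est@nUsed)) nrow(Xm) else est@nUsed
      if (est@status == "ok") values[i, j] <- est@value
    }
  }
  new("ProfileMatrix", values = values, statuses = statuses,
      nUsed = nUsed)
}

#' Impute missing cells of a profile matrix
#'
#' Deterministic chained least-squares imputation: missing cells start at
#' their column means, then each incomplete column is repeatedly
#' regressed on all other columns over the rows where it was observed
#' and its missing cells replaced by the regression prediction, until
#' the largest change falls below `tol` or `maxIter` sweeps. The
#' procedure is its own, fully specified scheme (not a clone of any
#' specific library's iterative imputer), and is deterministic given its
#' inputs.
#'
#' @param pm A [ProfileMatrix-class]; every column needs at least 2
#'   observed values.
#' @param maxIter Maximum sweeps (default 100).
#' @param tol Convergence threshold on the largest cell change.
#' @param seed Unused (kept for interface symmetry with the other batch
#'   operations).
#' @return A complete [ProfileMatrix-class]; imputed cells are marked
#'   `"ok"` in the status matrix (they are usable values downstream).
#' @examples
#' v <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, NA, 8))
#' st <- ifelse(is.na(v), "invalid_nan", "ok")
#' pm <- new("ProfileMatrix", values = v, statuses = st)
#' profileValues(imputeProfile(pm))
#' @export
imputeProfile <- function(pm, maxIter = 100L, tol = 1e-6, seed = 0L) {
  stopifnot(is(pm, "ProfileMatrix"))
  V <- pm@values
  miss <- is.na(V)
  if (!any(miss)) return(pm)
  if (ncol(V) < 2L) stop("imputation needs at least 2 methods")
  nObs <- colSums(!miss)
  if (any(nObs == 0))
    stop("method column(s) entirely missing: ",
         paste(colnames(V)[nObs == 0], collapse = ", "))
  if (any(nObs < 2L))
    stop("method column(s) with fewer than 2 observed values: ",
         paste(colnames(V)[nObs < 2L], collapse = ", "))
  W <- V
  mu <- colMeans(V, na.rm = TRUE)
  for (j in seq_len(ncol(W))) W[miss[, j], j] <- mu[j]
  for (iter in seq_len(maxIter)) {
    delta <- 0
    for (j in which(colSums(miss) > 0)) {
      obs <- !miss[, j]
      Zo <- cbind(1, W[obs, -j, drop = FALSE])
      beta <- qr.coef(qr(Zo), W[obs, j])
      beta[is.na(beta)] <- 0  # collinear predictors drop out
      pred <- cbind(1, W[!obs, -j, drop = FALSE]) %*% beta
      delta <- max(delta, max(abs(W[!obs, j] - pred)))
      W[!obs, j] <- pred
    }
    if (delta < tol) break
  }
  if (!all(is.finite(W))) stop("imputation produced non-finite values")
  st <- pm@statuses
  st[miss] <- "ok"
  new("ProfileMatrix", values = W, statuses = st, nUsed = pm@nUsed)
}

#' Consensus intrinsic dimension and profile PCA
#'
#' Scales each method column of a complete profile matrix to z-scores,
#' defines the consensus ID score of a dataset as the mean of its
#' z-scores across methods (negative for lower-dimensional, positive for
#' higher-dimensional datasets relative to the collection), and runs a
#' PCA of the z-scored profile, returning explained-variance fractions
#' and method loadings. The loading sign convention makes the
#' largest-magnitude loading of each component positive.
#'
#' @param pm A complete [ProfileMatrix-class] (impute first if needed)
#'   with at least 2 datasets (with exactly two, the consensus scores
#'   are equal in magnitude and opposite in sign by construction).
#' @return A [ConsensusResult-class].
#' @examples
#' coll <- lapply(1:4, function(i)
#'   generateManifold("hyperball", 200, list(d = i), seed = i))
#' names(coll) <- paste0("ball", 1:4)
#' cr <- consensusID(runProfile(coll, c("MLE", "TwoNN", "MOM")))
#' meanZ(cr)
#' @export
consensusID <- function(pm) {
  stopifnot(is(pm, "ProfileMatrix"))
  V <- pm@values
  if (any(is.na(V)))
    stop("profile matrix has missing cells; run imputeProfile() first")
  if (nrow(V) < 2L) stop("consensus needs at least 2 datasets")
  sds <- apply(V, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance method column(s): ",
         paste(colnames(V)[sds == 0], collapse = ", "))
  Z <- scale(V)
  attr(Z, "scaled:center") <- attr(Z, "scaled:scale") <- NULL
  pca <- prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  rot <- pca$rotation
  for (q in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, q])), q] < 0) rot[, q] <- -rot[, q]
  }
  new("ConsensusResult", zscores = Z, meanZ = rowMeans(Z),
      explainedVariance = ev, loadings = rot)
}

#' Correlation matrix between ID methods
#'
#' Pearson correlation of the method columns of a complete profile
#' matrix across datasets; symmetric with unit diagonal. On large
#' collections this separates PCA-based from nonlinear methods, and
#' fractal-flavored from concentration-of-measure methods.
#'
#' @param pm A complete [ProfileMatrix-class] with at least 3 datasets.
#' @return Methods x methods numeric correlation matrix.
#' @examples
#' coll <- lapply(1:4, function(i)
#'   generateManifold("hyperball", 200, list(d = i), seed = i))
#' methodCorrelation(runProfile(coll, c("MLE", "MOM", "TwoNN")))
#' @export
methodCorrelation <- function(pm) {
  stopifnot(is(pm, "ProfileMatrix"))
  V <- pm@values
  if (any(is.na(V)))
    stop("profile matrix has missing cells; run imputeProfile() first")
  if (nrow(V) < 3L) stop("correlation needs at least 3 datasets")
  sds <- apply(V, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance method column(s): ",
         paste(colnames(V)[sds == 0], collapse = ", "))
  cor(V)
}

#' Sensitivity of a method to feature redundancy
#'
#' Duplicates all columns of the matrix (`[X X]`) and reports the ratio
#' between the ID estimated on the duplicated and on the original
#' matrix. A perfectly redundancy-insensitive method has ratio 1; the
#' spectrum of `[X X]` is `{2 lambda_i} U {0}` so relative-eigenvalue
#' criteria are exactly invariant, while count-based spectral criteria
#' (Kaiser, broken stick, maxgap) can move. All pairwise distances scale
#' by `sqrt(2)`, so distance-ratio estimators are invariant up to
#' sampling noise.
#'
#' @param X Numeric matrix.
#' @param method Registered method tag.
#' @param seed Integer seed forwarded to the estimator.
#' @param params Parameter overrides forwarded to both runs.
#' @return A [SensitivityResult-class]; the ratio is NA unless both runs
#'   have status `"ok"`.
#' @examples
#' X <- samplePoints(generateManifold("gaussian", 200, list(d = 5),
#'                                    seed = 1))
#' redundancySensitivity(X, "lPCA_FO")
#' @export
redundancySensitivity <- function(X, method, seed = 0L, params = list()) {
  X <- asDataMatrix(X)
  run <- function(M) tryCatch(
    estimateGlobal(M, method, params = params, seed = seed),
    error = function(e) newIDEstimate(method, NA_real_,
                                      degenerate = TRUE))
  e1 <- run(X)
  e2 <- run(cbind(X, X))
  ratio <- if (e1@status == "ok" && e2@status == "ok")
    e2@value / e1@value else NA_real_
  new("SensitivityResult", method = method,
      idOriginal = e1@value, idDuplicated = e2@value, ratio = ratio,
      statusOriginal = e1@status, statusDuplicated = e2@status)
}

#' Fit the multiplicative runtime model
#'
#' Fits `Time = c * Nobj^alpha * Nvar^beta` to timing records by
#' ordinary least squares on `ln seconds`, returning the constant, the
#' two exponents and the R-squared of the log-linear fit. Predictions at
#' arbitrary matrix shapes are available through [predictTime()].
#'
#' @param records Data frame with columns `Nobj`, `Nvar`, `seconds`
#'   (all positive); at least 3 rows with at least 2 distinct `Nobj`
#'   and 2 distinct `Nvar`.
#' @return A [TimeModelFit-class].
#' @examples
#' rec <- expand.grid(Nobj = c(100, 1000), Nvar = c(10, 100))
#' rec$seconds <- 0.01 * rec$Nobj^1.5 * rec$Nvar^0.5
#' fitTimeModel(rec)
#' @export
fitTimeModel <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("Nobj", "Nvar", "seconds") %in% names(records)))
  if (nrow(records) < 3L) stop("need at least 3 timing records")
  if (length(unique(records$Nobj)) < 2L)
    stop("need at least 2 distinct Nobj values")
  if (length(unique(records$Nvar)) < 2L)
    stop("need at least 2 distinct Nvar values; ",
         "add timing runs at another feature count")
  if (any(records$seconds <= 0)) stop("seconds must be positive")
  fit <- lm(log(seconds) ~ log(Nobj) + log(Nvar), data = records)
  cf <- coef(fit)
  ## R^2 computed directly (summary.lm warns on noiseless fits)
  y <- log(records$seconds)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  new("TimeModelFit", c = exp(unname(cf[1L])), alpha = unname(cf[2L]),
      beta = unname(cf[3L]), rSquared = r2)
}

#' Predict runtime from a fitted multiplicative model
#'
#' @param fit A [TimeModelFit-class].
#' @param Nobj,Nvar Matrix shape(s) to predict for (vectorized).
#' @return Predicted seconds.
#' @examples
#' rec <- expand.grid(Nobj = c(100, 1000), Nvar = c(10, 100))
#' rec$seconds <- 0.01 * rec$Nobj^1.5 * rec$Nvar^0.5
#' predictTime(fitTimeModel(rec), 5000, 50)
#' @export
predictTime <- function(fit, Nobj, Nvar) {
  stopifnot(is(fit, "TimeModelFit"))
  fit@c * Nobj^fit@alpha * Nvar^fit@beta
}

#' Coefficient of variation of ID estimates
#'
#' Trivial helper for the uniformity analysis across groups of similar
#' datasets: the standard deviation over the mean of a method's
#' estimates within a group.
#'
#' @param x Numeric vector of estimates (NA dropped).
#' @return `sd(x)/mean(x)`.
#' @examples
#' coefVariation(c(5.1, 4.9, 5.3))
#' @export
coefVariation <- function(x) {
  x <- x[is.finite(x)]
  sd(x) / mean(x)
}
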
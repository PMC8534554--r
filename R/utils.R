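#' @useDynLib idest, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats cov dist integrate lm optimize prcomp runif rnorm
#'   uniroot var sd cor coef pbeta setNames
#' @importFrom utils head read.csv write.csv
NULL

## Valid status codes for an estimate; "ok" means finite and > 0.
.ID_STATUSES <- c("ok", "invalid_nan", "invalid_negative",
                  "invalid_infinite", "degenerate_input")

## Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
## All stochastic code in the package funnels through this.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

## Coerce input to a validated numeric data matrix (M x p, finite entries).
asDataMatrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop("X must be a numeric matrix or data frame")
  storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop("X must have at least 2 rows")
  if (ncol(X) < 1L) stop("X must have at least 1 column")
  if (!all(is.finite(X))) stop("X must contain only finite values")
  X
}

## Merge user params over defaults, rejecting unknown names.
mergeParams <- function(defaults, params) {
  if (length(params) == 0L) return(defaults)
  bad <- setdiff(names(params), names(defaults))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  defaults[names(params)] <- params
  defaults
}

#' Read a data matrix from delimited text
#'
#' Reads a dense numeric observations-by-features matrix from a CSV or TSV
#' file, with an optional header row and an optional first column of row
#' identifiers.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator; `","` for CSV (default), `"\t"` for TSV.
#' @param header Logical; does the first line name the features?
#' @param rowIds Logical; is the first column a row-identifier column?
#' @return A numeric matrix with `dimnames` carrying any names found.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(a = 1:3, b = 4:6), tf, row.names = FALSE)
#' readDataMatrix(tf)
#' @export
readDataMatrix <- function(path, sep = ",", header = TRUE, rowIds = FALSE) {
  df <- read.csv(path, sep = sep, header = header,
                 check.names = FALSE, stringsAsFactors = FALSE)
  if (rowIds) {
    rn <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
    rownames(df) <- rn
  }
  asDataMatrix(df)
}
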
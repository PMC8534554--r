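#' Write / read a profile matrix as CSV
#'
#' `writeProfileMatrix` writes the values (first column `dataset`) to
#' `path` and the parallel status matrix to `statusPath` (default:
#' `path` with a `.status.csv` suffix). `readProfileMatrix` reads the
#' pair back; when the status file is absent, statuses are inferred from
#' missingness.
#'
#' @param pm A [ProfileMatrix-class].
#' @param path CSV path for the values.
#' @param statusPath CSV path for the statuses.
#' @return `readProfileMatrix` returns a [ProfileMatrix-class];
#'   `writeProfileMatrix` returns `path` invisibly.
#' @examples
#' v <- cbind(MLE = c(2.1, 3.2, 4.0), MOM = c(1.9, 3.1, 4.2))
#' rownames(v) <- paste0("d", 1:3)
#' pm <- new("ProfileMatrix", values = v,
#'           statuses = matrix("ok", 3, 2, dimnames = dimnames(v)))
#' tf <- tempfile(fileext = ".csv")
#' writeProfileMatrix(pm, tf)
#' profileValues(readProfileMatrix(tf))
#' @export
writeProfileMatrix <- function(pm, path,
                               statusPath = sub("\\.csv$", ".status.csv",
                                                path)) {
  stopifnot(is(pm, "ProfileMatrix"))
  df <- data.frame(dataset = rownames(pm@values), pm@values,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  dfs <- data.frame(dataset = rownames(pm@statuses), pm@statuses,
                    check.names = FALSE)
  write.csv(dfs, statusPath, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfileMatrix
#' @export
readProfileMatrix <- function(path,
                              statusPath = sub("\\.csv$", ".status.csv",
                                               path)) {
  df <- read.csv(path, check.names = FALSE)
  v <- as.matrix(df[, -1L, drop = FALSE])
  rownames(v) <- df[[1L]]
  storage.mode(v) <- "double"
  if (file.exists(statusPath)) {
    dfs <- read.csv(statusPath, check.names = FALSE)
    st <- as.matrix(dfs[, -1L, drop = FALSE])
    rownames(st) <- dfs[[1L]]
  } else {
    st <- ifelse(is.na(v), "invalid_nan", "ok")
  }
  new("ProfileMatrix", values = v, statuses = st)
}

## Plain-list view of an estimate, for JSON output.
estimateToList <- function(est) {
  stopifnot(is(est, "IDEstimate"))
  keep <- Filter(function(v) is.atomic(v) && length(v) <= 50,
                 est@params)
  list(method = est@method,
       value = if (is.na(est@value)) NULL else est@value,
       status = est@status, params = keep,
       n_used = if (is.na(est@nUsed)) NULL else est@nUsed)
}
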
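#' Eigenvalue-spectrum (PCA) dimension criteria
#'
#' Estimates dimension from a covariance eigenvalue spectrum by one of
#' seven classical criteria. With `l_i = lambda_i / sum(lambda)` the
#' normalized spectrum and `p'` the number of nonzero eigenvalues:
#'
#' \describe{
#'   \item{`FO`}{(Fukunaga--Olsen) number of eigenvalues with
#'     `lambda_i / lambda_1 > alphaFO`.}
#'   \item{`Fan`}{smallest `i` at which both a large consecutive gap
#'     (`lambda_i / lambda_{i+1} > fanRatioR`) and sufficient cumulative
#'     normalized variance (`>= fanCumC`) hold; `p'` if never. A
#'     rank-deficient spectrum always triggers at `i = p'` (the gap into
#'     the zero block is infinite).}
#'   \item{`maxgap`}{position of the largest consecutive-eigenvalue ratio
#'     `lambda_i / lambda_{i+1}` (ratios, not differences, so the
#'     criterion is scale-invariant); for a rank-deficient spectrum the
#'     infinite gap into the zero block wins, giving `p'`.}
#'   \item{`ratio`}{smallest `i` whose cumulative normalized sum reaches
#'     `ratioTau` (explained-variance threshold).}
#'   \item{`participation_ratio`}{`(sum lambda)^2 / sum lambda^2`, a
#'     continuous spectrum-flatness measure, not rounded by default.}
#'   \item{`Kaiser`}{number of eigenvalues strictly above the mean
#'     eigenvalue (ties at the mean excluded).}
#'   \item{`broken_stick`}{length of the maximal initial run with `l_i`
#'     above the broken-stick null `b_i = (1/p) * sum_{j=i}^{p} 1/j`.}
#' }
#'
#' Counting criteria report at least dimension 1 on any nonzero spectrum
#' (a perfectly flat spectrum would otherwise give 0 under the strict
#' Kaiser and broken-stick rules).
#'
#' All criteria are invariant to multiplying the spectrum by a positive
#' constant. This operation is a pure spectrum-to-dimension map: the
#' global PCA ID applies it to the full-data spectrum, while the local PCA
#' ID applies it per neighborhood through [estimateLocal()].
#'
#' @param spec An [EigenSpectrum-class], or a numeric matrix whose
#'   covariance spectrum is taken first.
#' @param variant One of `"FO"`, `"Fan"`, `"maxgap"`, `"ratio"`,
#'   `"participation_ratio"`, `"Kaiser"`, `"broken_stick"`.
#' @param alphaFO FO relative-eigenvalue threshold in (0,1), default 0.05.
#' @param fanRatioR Fan consecutive-ratio threshold (> 1), default 10.
#' @param fanCumC Fan cumulative-variance threshold in (0,1), default 0.8.
#' @param ratioTau Explained-variance threshold in (0,1), default 0.95.
#' @param round Round the participation ratio to an integer? Default off.
#' @return An [IDEstimate-class]. An all-zero spectrum gives status
#'   `"degenerate_input"`; variants needing a consecutive ratio return 1
#'   (status ok) when only one nonzero eigenvalue exists.
#' @examples
#' pcaDimension(new("EigenSpectrum", lambdas = c(1, 0.5, 0.04)), "FO")
#' @export
pcaDimension <- function(spec,
                         variant = c("FO", "Fan", "maxgap", "ratio",
                                     "participation_ratio", "Kaiser",
                                     "broken_stick"),
                         alphaFO = 0.05, fanRatioR = 10, fanCumC = 0.8,
                         ratioTau = 0.95, round = FALSE) {
  variant <- match.arg(variant)
  stopifnot(alphaFO > 0, alphaFO < 1, fanRatioR > 1,
            fanCumC > 0, fanCumC < 1, ratioTau > 0, ratioTau < 1)
  if (is.matrix(spec) || is.data.frame(spec))
    spec <- covarianceSpectrum(spec)
  stopifnot(is(spec, "EigenSpectrum"))
  l <- spec@lambdas
  p <- length(l)
  params <- list(variant = variant, alphaFO = alphaFO,
                 fanRatioR = fanRatioR, fanCumC = fanCumC,
                 ratioTau = ratioTau)
  tag <- paste0("lPCA_", switch(variant, FO = "FO", Fan = "Fan",
                                maxgap = "maxgap", ratio = "ratio",
                                participation_ratio = "PR",
                                Kaiser = "Kaiser", broken_stick = "BS"))
  total <- sum(l)
  if (total == 0)
    return(newIDEstimate(tag, NA_real_, params, degenerate = TRUE))
  np <- sum(l > 0)
  ln <- l / total
  d <- switch(variant,
    FO = sum(l / l[1] > alphaFO),
    Fan = {
      if (np == 1L) 1L else {
        cum <- cumsum(ln)
        ## both a large consecutive-eigenvalue gap and enough cumulative
        ## variance are required; a rank-deficient spectrum always
        ## satisfies the pair at i = p' (infinite gap, full variance)
        ratios <- l[seq_len(np)] /
          pmax(l[seq_len(np) + 1L], 0)[seq_len(np)]
        ratios[is.na(ratios)] <- Inf  # lambda_{p+1} does not exist
        hit <- which(ratios > fanRatioR & cum[seq_len(np)] >= fanCumC)
        if (length(hit)) hit[1L] else np
      }
    },
    maxgap = {
      if (np == 1L) 1L
      else if (np < p) np  # the gap into the zero block is infinite
      else which.max(l[seq_len(p - 1L)] / l[seq_len(p - 1L) + 1L])
    },
    ratio = which(cumsum(ln) >= ratioTau - 1e-12)[1L],
    participation_ratio = {
      pr <- total^2 / sum(l^2)
      if (round) base::round(pr) else pr
    },
    ## counting criteria report at least 1 on a nonzero spectrum
    Kaiser = max(1L, sum(l > mean(l))),
    broken_stick = {
      b <- rev(cumsum(1 / rev(seq_len(p)))) / p
      above <- ln > b
      run <- if (!above[1L]) 0L else {
        stop_ <- which(!above)
        if (length(stop_)) stop_[1L] - 1L else p
      }
      max(1L, run)
    })
  newIDEstimate(tag, as.numeric(d), params, nUsed = NA_integer_)
}
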
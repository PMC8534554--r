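#' Accessors for idest S4 objects
#'
#' Small accessor generics exposing slots of the package's S4 classes:
#' `idValue`, `idStatus`, `idMethod` and `nUsed` for [IDEstimate-class]
#' (and their vectorized forms on [LocalIDField-class]); `neighborIndices`
#' and `neighborDistances` for [NeighborTable-class]; `eigenvalues` for
#' [EigenSpectrum-class]; `samplePoints`, `segmentLabels` and
#' `intrinsicDim` for [ManifoldSample-class]; `profileValues` and
#' `profileStatuses` for [ProfileMatrix-class]; `meanZ`,
#' `explainedVariance` and `consensusLoadings` for
#' [ConsensusResult-class].
#'
#' @param object An idest S4 object.
#' @return The slot contents; see the class documentation for shapes.
#' @name idest-accessors
#' @examples
#' est <- estimateGlobal(generateManifold("hyperball", 200,
#'                                        list(d = 2), seed = 1), "MLE")
#' idValue(est); idStatus(est); nUsed(est)
NULL

#' @rdname idest-accessors
#' @export
setGeneric("idValue", function(object) standardGeneric("idValue"))
#' @rdname idest-accessors
#' @export
setGeneric("idStatus", function(object) standardGeneric("idStatus"))
#' @rdname idest-accessors
#' @export
setGeneric("idMethod", function(object) standardGeneric("idMethod"))
#' @rdname idest-accessors
#' @export
setGeneric("nUsed", function(object) standardGeneric("nUsed"))
#' @rdname idest-accessors
#' @export
setGeneric("neighborIndices",
           function(object) standardGeneric("neighborIndices"))
#' @rdname idest-accessors
#' @export
setGeneric("neighborDistances",
           function(object) standardGeneric("neighborDistances"))
#' @rdname idest-accessors
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))
#' @rdname idest-accessors
#' @export
setGeneric("samplePoints", function(object) standardGeneric("samplePoints"))
#' @rdname idest-accessors
#' @export
setGeneric("segmentLabels",
           function(object) standardGeneric("segmentLabels"))
#' @rdname idest-accessors
#' @export
setGeneric("intrinsicDim", function(object) standardGeneric("intrinsicDim"))
#' @rdname idest-accessors
#' @export
setGeneric("profileValues",
           function(object) standardGeneric("profileValues"))
#' @rdname idest-accessors
#' @export
setGeneric("profileStatuses",
           function(object) standardGeneric("profileStatuses"))
#' @rdname idest-accessors
#' @export
setGeneric("profileNUsed",
           function(object) standardGeneric("profileNUsed"))
#' @rdname idest-accessors
#' @export
setGeneric("meanZ", function(object) standardGeneric("meanZ"))
#' @rdname idest-accessors
#' @export
setGeneric("explainedVariance",
           function(object) standardGeneric("explainedVariance"))
#' @rdname idest-accessors
#' @export
setGeneric("consensusLoadings",
           function(object) standardGeneric("consensusLoadings"))

#' @rdname idest-accessors
setMethod("idValue", "IDEstimate", function(object) object@value)
#' @rdname idest-accessors
setMethod("idStatus", "IDEstimate", function(object) object@status)
#' @rdname idest-accessors
setMethod("idMethod", "IDEstimate", function(object) object@method)
#' @rdname idest-accessors
setMethod("nUsed", "IDEstimate", function(object) object@nUsed)
#' @rdname idest-accessors
setMethod("idValue", "LocalIDField", function(object) object@values)
#' @rdname idest-accessors
setMethod("idStatus", "LocalIDField", function(object) object@statuses)
#' @rdname idest-accessors
setMethod("idMethod", "LocalIDField", function(object) object@method)
#' @rdname idest-accessors
setMethod("neighborIndices", "NeighborTable",
          function(object) object@indices)
#' @rdname idest-accessors
setMethod("neighborDistances", "NeighborTable",
          function(object) object@distances)
#' @rdname idest-accessors
setMethod("eigenvalues", "EigenSpectrum", function(object) object@lambdas)
#' @rdname idest-accessors
setMethod("samplePoints", "ManifoldSample", function(object) object@points)
#' @rdname idest-accessors
setMethod("segmentLabels", "ManifoldSample",
          function(object) if (length(object@labels)) object@labels else NULL)
#' @rdname idest-accessors
setMethod("intrinsicDim", "ManifoldSample",
          function(object) object@intrinsicDim)
#' @rdname idest-accessors
setMethod("profileValues", "ProfileMatrix", function(object) object@values)
#' @rdname idest-accessors
setMethod("profileStatuses", "ProfileMatrix",
          function(object) object@statuses)
#' @rdname idest-accessors
setMethod("profileNUsed", "ProfileMatrix",
          function(object) object@nUsed)
#' @rdname idest-accessors
setMethod("meanZ", "ConsensusResult", function(object) object@meanZ)
#' @rdname idest-accessors
setMethod("explainedVariance", "ConsensusResult",
          function(object) object@explainedVariance)
#' @rdname idest-accessors
setMethod("consensusLoadings", "ConsensusResult",
          function(object) object@loadings)

setMethod("show", "IDEstimate", function(object) {
  cat("IDEstimate [", object@method, "]\n", sep = "")
  cat("  value :", if (is.na(object@value)) "NA" else
    format(object@value, digits = 6), "\n")
  cat("  status:", object@status, " (n used:", object@nUsed, ")\n")
})

setMethod("show", "NeighborTable", function(object) {
  cat("NeighborTable: ", nrow(object@indices), " points, k = ",
      object@k, "\n", sep = "")
})

setMethod("show", "EigenSpectrum", function(object) {
  l <- object@lambdas
  cat("EigenSpectrum: p = ", length(l), ", nonzero = ", sum(l > 0),
      "\n  head: ", paste(format(head(l, 5), digits = 4), collapse = " "),
      "\n", sep = "")
})

setMethod("show", "LocalIDField", function(object) {
  ok <- object@statuses == "ok"
  cat("LocalIDField [", object@method, "], k = ", object@k, ": ",
      length(object@values), " points, ", sum(ok), " valid\n", sep = "")
  if (any(ok))
    cat("  mean local ID:",
        format(mean(object@values[ok]), digits = 5), "\n")
})

setMethod("show", "ManifoldSample", function(object) {
  cat("ManifoldSample '", object@name, "': ", nrow(object@points),
      " points in ", object@ambientDim, "-D, intrinsic dim ",
      paste(object@intrinsicDim, collapse = "/"),
      ", seed ", object@seed, "\n", sep = "")
})

setMethod("show", "ProfileMatrix", function(object) {
  v <- object@values
  cat("ProfileMatrix: ", nrow(v), " datasets x ", ncol(v), " methods, ",
      sum(is.na(v)), " missing\n", sep = "")
})

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult: ", nrow(object@zscores), " datasets, ",
      ncol(object@zscores), " methods; PC1 explains ",
      format(100 * object@explainedVariance[1], digits = 4), "%\n",
      sep = "")
})

setMethod("show", "TimeModelFit", function(object) {
  cat("TimeModelFit: Time = ", format(object@c, digits = 4),
      " * Nobj^", format(object@alpha, digits = 4),
      " * Nvar^", format(object@beta, digits = 4),
      "  (R^2 = ", format(object@rSquared, digits = 4), ")\n", sep = "")
})

setMethod("show", "SensitivityResult", function(object) {
  cat("SensitivityResult [", object@method, "]: ",
      format(object@idOriginal, digits = 5), " -> ",
      format(object@idDuplicated, digits = 5), ", ratio ",
      format(object@ratio, digits = 5), "\n", sep = "")
})
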
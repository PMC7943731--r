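#' Accessors for package classes
#'
#' \code{pixels} extracts the intensity matrix of a [Phantom-class];
#' \code{sideLength} its side in pixels; \code{phantomLabel} its provenance
#' tag.  For a [MeasurementMatrix-class], \code{entries} returns the dense
#' operator, \code{matrixKind} its kind and \code{undersamplingRatio} the
#' ratio \eqn{M/N^2}.
#'
#' @param object a package object.
#' @return the slot value.
#' @name accessors
#' @aliases pixels sideLength phantomLabel entries matrixKind
#'   undersamplingRatio
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("sideLength", function(object) standardGeneric("sideLength"))
#' @rdname accessors
#' @export
setGeneric("phantomLabel", function(object) standardGeneric("phantomLabel"))
#' @rdname accessors
#' @export
setGeneric("entries", function(object) standardGeneric("entries"))
#' @rdname accessors
#' @export
setGeneric("matrixKind", function(object) standardGeneric("matrixKind"))
#' @rdname accessors
#' @export
setGeneric("undersamplingRatio",
           function(object) standardGeneric("undersamplingRatio"))

#' @rdname measure
#' @export
setGeneric("measure", function(K, x, noiseSigma = 0, seed = NULL)
  standardGeneric("measure"))

#' @rdname proxyImage
#' @export
setGeneric("proxyImage", function(K, v) standardGeneric("proxyImage"))

#' @rdname reconstruct
#' @export
setGeneric("reconstruct", function(model, v) standardGeneric("reconstruct"))

#' @rdname accessors
#' @export
setMethod("pixels", "Phantom", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("sideLength", "Phantom", function(object) nrow(object@pixels))
#' @rdname accessors
#' @export
setMethod("phantomLabel", "Phantom", function(object) object@label)
#' @rdname accessors
#' @export
setMethod("entries", "MeasurementMatrix", function(object) object@entries)
#' @rdname accessors
#' @export
setMethod("matrixKind", "MeasurementMatrix", function(object) object@kind)
#' @rdname accessors
#' @export
setMethod("undersamplingRatio", "MeasurementMatrix",
          function(object) object@undersamplingRatio)
#' @rdname accessors
#' @export
setMethod("sideLength", "MeasurementMatrix",
          function(object) as.integer(object@gridSide))

setMethod("show", "Phantom", function(object) {
  p <- object@pixels
  cat(sprintf("Phantom %dx%d  range [%.3f, %.3f]  label: %s\n",
              nrow(p), ncol(p), min(p), max(p),
              if (nzchar(object@label)) object@label else "<none>"))
})

setMethod("show", "MeasurementMatrix", function(object) {
  cat(sprintf("MeasurementMatrix kind=%s  %d x %d  ratio=%.4g\n",
              object@kind, nrow(object@entries), ncol(object@entries),
              object@undersamplingRatio))
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit: %d train / %d test (fraction %.2f)\n",
              length(object@train), length(object@test),
              object@trainFraction))
})

setMethod("show", "RIPReport", function(object) {
  cat(sprintf(
    "RIPReport s=%d trials=%d  ratio in [%.4f, %.4f]  delta-hat=%.4f\n",
    object@sparsity, object@trials, object@ratioMin, object@ratioMax,
    object@deltaHat))
})

setMethod("show", "TVSolution", function(object) {
  n <- length(object@objectiveTrace)
  cat(sprintf("TVSolution: %d iterations, %s, objective %.6g -> %.6g\n",
              object@iterationsRun,
              if (object@converged) "converged" else "not converged",
              object@objectiveTrace[1], object@objectiveTrace[n]))
})

setMethod("show", "ReconModel", function(object) {
  tr <- nrow(object@trainHistory)
  cat(sprintf(
    "ReconModel family=%s  N=%d  ratio=%.3g  %s\n",
    object@family, object@matrix@gridSide,
    object@matrix@undersamplingRatio,
    if (tr > 0) sprintf("trained %d epochs (final loss %.4g)", tr,
                        object@trainHistory$loss[tr]) else "untrained"))
})
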
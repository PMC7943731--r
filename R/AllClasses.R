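#' @import methods
#' @importFrom stats rnorm runif sd quantile
#' @importFrom utils write.csv read.csv packageVersion modifyList
#' @useDynLib PATRecon, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Phantom: a square reconstruction target image
#'
#' A \code{Phantom} holds a square 2-D intensity image, the reconstruction
#' target \eqn{x} of the measurement model \eqn{y = Kx}.  Pipeline images are
#' normalised to the closed interval \eqn{[-1, 1]}; intermediate images (for
#' example the transpose proxy \eqn{K^T v}) may exceed that range, so the
#' class validity only enforces squareness, a minimum side of 16 pixels and
#' finite values.
#'
#' @slot pixels numeric matrix, square, side \eqn{\ge} 16.
#' @slot label character scalar, free-text provenance tag.
#'
#' @seealso [generatePhantom()], [normalizeImage()]
#' @export
setClass("Phantom",
  representation(pixels = "matrix", label = "character"),
  prototype(pixels = matrix(0, 16, 16), label = "")
)

setValidity("Phantom", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (nrow(p) != ncol(p)) return("pixels must be square")
  if (nrow(p) < 2) return("side length must be at least 2")
  if (!all(is.finite(p))) return("pixels must be finite")
  if (length(object@label) != 1) return("label must be a single string")
  TRUE
})

#' Augmentation recipe for phantom images
#'
#' Describes the deterministic augmentation set applied to each image:
#' a finite set of rotation angles (degrees, counter-clockwise), a subset of
#' \code{"horizontal"}/\code{"vertical"} flips, and a centre-crop fraction.
#' With crop fraction below 1, every rotated/flipped output is additionally
#' centre-cropped to that fraction of the side and bilinearly resized back,
#' so the output count is always \code{length(rotations) * (1 + length(flips))}.
#'
#' @slot rotations numeric vector of angles in degrees.
#' @slot flips character vector, subset of \code{c("horizontal", "vertical")}.
#' @slot cropFraction numeric in (0, 1]; fraction of the side retained.
#' @slot seed integer seed (reserved for randomised augmentations).
#' @export
setClass("AugmentationSpec",
  representation(rotations = "numeric", flips = "character",
                 cropFraction = "numeric", seed = "integer"),
  prototype(rotations = 0, flips = character(0), cropFraction = 1,
            seed = 1L)
)

setValidity("AugmentationSpec", function(object) {
  if (length(object@rotations) < 1) return("at least one rotation (use 0)")
  if (!all(object@flips %in% c("horizontal", "vertical")))
    return("flips must be a subset of 'horizontal', 'vertical'")
  if (anyDuplicated(object@flips)) return("duplicate flips")
  cf <- object@cropFraction
  if (length(cf) != 1 || !is.finite(cf) || cf <= 0 || cf > 1)
    return("cropFraction must lie in (0, 1]")
  TRUE
})

#' Train/test partition of a phantom dataset
#'
#' @slot train list of [Phantom-class] objects.
#' @slot test list of [Phantom-class] objects.
#' @slot trainFraction numeric, requested training fraction.
#' @export
setClass("DatasetSplit",
  representation(train = "list", test = "list", trainFraction = "numeric")
)

setValidity("DatasetSplit", function(object) {
  if (!all(vapply(c(object@train, object@test),
                  function(p) is(p, "Phantom"), logical(1))))
    return("train and test must contain Phantom objects")
  n <- length(object@train) + length(object@test)
  if (n == 0) return("empty split")
  f <- length(object@train) / n
  if (abs(f - object@trainFraction) * n > 1 + 1e-9)
    return("train fraction off by more than one item")
  TRUE
})

#' Ring-array acquisition geometry
#'
#' Geometry of a circular transducer array surrounding a square imaging
#' grid, used to build the physical time- and frequency-domain measurement
#' kernels.  Transducers are equally spaced on the ring; pixel centres must
#' lie strictly inside the ring so that every pixel-transducer distance is
#' positive.
#'
#' @slot numTransducers integer, number of ring elements \eqn{p}.
#' @slot ringRadius numeric, ring radius in mm.
#' @slot soundSpeed numeric, speed of sound \eqn{c} in mm/us.
#' @slot gridSide integer, image side \eqn{N} in pixels.
#' @slot gridExtent numeric, physical side length of the imaging square (mm).
#' @slot timeSamples integer, number of time samples \eqn{q_s}.
#' @slot dt numeric, time step in us.
#' @slot wavenumbers numeric vector of wavenumbers \eqn{k_n} (1/mm) for the
#'   frequency-domain kernel.
#' @export
setClass("PATGeometry",
  representation(numTransducers = "integer", ringRadius = "numeric",
                 soundSpeed = "numeric", gridSide = "integer",
                 gridExtent = "numeric", timeSamples = "integer",
                 dt = "numeric", wavenumbers = "numeric")
)

setValidity("PATGeometry", function(object) {
  if (object@numTransducers < 1) return("need at least one transducer")
  if (object@ringRadius <= 0) return("ringRadius must be positive")
  if (object@soundSpeed <= 0) return("soundSpeed must be positive")
  if (object@gridSide < 2) return("gridSide must be at least 2")
  if (object@gridExtent <= 0) return("gridExtent must be positive")
  if (object@timeSamples < 1) return("timeSamples must be at least 1")
  if (object@dt <= 0) return("dt must be positive")
  if (any(object@wavenumbers < 0)) return("wavenumbers must be >= 0")
  # strict-interior condition: the farthest pixel centre (half diagonal)
  # must be inside the ring
  half <- object@gridExtent / 2
  ddiag <- sqrt(2) * half * (1 - 1 / object@gridSide)
  if (ddiag >= object@ringRadius)
    return("grid corners reach the transducer ring; shrink gridExtent")
  TRUE
})

#' Linear measurement operator
#'
#' An \eqn{M \times N^2} linear operator \eqn{K} mapping the row-major
#' vectorisation of an \eqn{N \times N} image to a length-\eqn{M}
#' measurement vector.  Three kinds are supported: \code{"gaussian"}
#' (random i.i.d. entries, variance \eqn{1/M}), \code{"pat_time"} (the
#' discretised spherical-delay kernel), and \code{"pat_freq"} (the complex
#' frequency-domain kernel).
#'
#' @slot entries numeric or complex matrix, \eqn{M \times N^2}.
#' @slot kind character, one of \code{"gaussian"}, \code{"pat_time"},
#'   \code{"pat_freq"}.
#' @slot gridSide integer, image side \eqn{N}.
#' @slot undersamplingRatio numeric, \eqn{M / N^2}.
#' @slot geometry a [PATGeometry-class] or \code{NULL} (gaussian kind).
#' @slot seed integer or NA.
#' @export
setClass("MeasurementMatrix",
  representation(entries = "matrix", kind = "character",
                 gridSide = "integer", undersamplingRatio = "numeric",
                 geometry = "ANY", seed = "integer")
)

setValidity("MeasurementMatrix", function(object) {
  if (!object@kind %in% c("gaussian", "pat_time", "pat_freq"))
    return("unknown matrix kind")
  n2 <- as.double(object@gridSide)^2
  if (ncol(object@entries) != n2)
    return("column count must equal gridSide^2")
  if (object@kind == "gaussian" && is.complex(object@entries))
    return("gaussian matrices must be real")
  if (object@kind == "pat_freq" && !is.complex(object@entries))
    return("pat_freq matrices must be complex")
  r <- nrow(object@entries) / n2
  if (abs(r - object@undersamplingRatio) > 1e-12)
    return("undersamplingRatio must equal M / N^2 exactly")
  TRUE
})

#' Measurement vector
#'
#' The data vector \eqn{v = Kx} (plus optional additive Gaussian noise)
#' produced by applying a [MeasurementMatrix-class] to a phantom.
#'
#' @slot values numeric or complex vector of length \eqn{M}.
#' @slot sourceMatrixId character identifier of the generating matrix.
#' @slot noiseSigma numeric, standard deviation of the added noise.
#' @export
setClass("MeasurementVector",
  representation(values = "ANY", sourceMatrixId = "character",
                 noiseSigma = "numeric")
)

setValidity("MeasurementVector", function(object) {
  if (!(is.numeric(object@values) || is.complex(object@values)))
    return("values must be numeric or complex")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  TRUE
})

#' Empirical restricted-isometry report
#'
#' Monte-Carlo estimate of the restricted-isometry constant
#' \eqn{\hat\delta_s} of an operator: over random \eqn{s}-sparse unit
#' vectors \eqn{\theta}, records the extremes of
#' \eqn{\|K\theta\|^2 / \|\theta\|^2} and reports
#' \eqn{\hat\delta = \max(1 - r_{min}, r_{max} - 1)}.
#'
#' @slot sparsity integer \eqn{s}.
#' @slot trials integer, number of random draws.
#' @slot deltaHat numeric, estimated RIP constant.
#' @slot ratioMin,ratioMax numeric, extreme norm ratios observed.
#' @export
setClass("RIPReport",
  representation(sparsity = "integer", trials = "integer",
                 deltaHat = "numeric", ratioMin = "numeric",
                 ratioMax = "numeric")
)

#' Total-variation reconstruction result
#'
#' @slot image a [Phantom-class], the reconstructed image.
#' @slot objectiveTrace numeric vector, objective value per iteration.
#' @slot iterationsRun integer.
#' @slot converged logical.
#' @export
setClass("TVSolution",
  representation(image = "Phantom", objectiveTrace = "numeric",
                 iterationsRun = "integer", converged = "logical")
)

#' Learned reconstruction model
#'
#' Couples a fixed (non-trained) transpose-proxy stage \eqn{K^T} with a
#' trainable convolutional network mapping the \eqn{N \times N} proxy image
#' to an \eqn{N \times N} reconstruction.
#'
#' @slot family character, one of \code{"cnn3"}, \code{"unet"},
#'   \code{"resunet"}.
#' @slot arch list, architecture hyper-parameters (depth, baseChannels,
#'   useBatchnorm).
#' @slot params list of weight arrays (flat, named).
#' @slot matrix the [MeasurementMatrix-class] defining the proxy stage.
#' @slot trainHistory data.frame with columns \code{epoch}, \code{loss}.
#' @slot config list, training provenance.
#' @slot seed integer, weight-initialisation seed.
#' @export
setClass("ReconModel",
  representation(family = "character", arch = "list", params = "list",
                 matrix = "MeasurementMatrix", trainHistory = "data.frame",
                 config = "list", seed = "integer")
)

setValidity("ReconModel", function(object) {
  if (!object@family %in% c("cnn3", "unet", "resunet"))
    return("unknown network family")
  TRUE
})
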
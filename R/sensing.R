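#' Construct a ring-array geometry
#'
#' Defaults mirror a full-view small-animal scanner: 512 elements on an
#' 80-mm-diameter ring, speed of sound 1.5 mm/us, a 50-mm imaging square
#' and 40 MS/s sampling.  \code{deskGeometry()} is a scaled-down preset
#' (fewer transducers, coarser grid and time axis) for CPU-scale tests;
#' both satisfy the strict-interior pixel condition.
#'
#' The wavenumber grid for the frequency-domain kernel defaults to
#' \code{freqSamples} frequencies equally spaced in (0, 5] MHz (the
#' transducer centre frequency), converted to wavenumbers
#' \eqn{k_n = 2\pi f_n / c}.
#'
#' @param numTransducers integer, ring elements.
#' @param ringRadius numeric, mm.
#' @param soundSpeed numeric, mm/us.
#' @param gridSide integer, image side in pixels.
#' @param gridExtent numeric, physical image side, mm.
#' @param timeSamples integer, time samples per channel.
#' @param dt numeric, time step, us.
#' @param wavenumbers numeric vector 1/mm, or \code{NULL} to derive from
#'   \code{freqSamples}.
#' @param freqSamples integer, number of frequencies when
#'   \code{wavenumbers} is \code{NULL}.
#' @return a [PATGeometry-class].
#' @export
patGeometry <- function(numTransducers = 512L, ringRadius = 40,
                        soundSpeed = 1.5, gridSide = 128L,
                        gridExtent = 50, timeSamples = NULL, dt = 0.025,
                        wavenumbers = NULL, freqSamples = 32L) {
  if (is.null(timeSamples)) {
    # cover the farthest pixel-transducer travel time
    tmax <- (ringRadius + gridExtent / sqrt(2)) / soundSpeed
    timeSamples <- as.integer(ceiling(tmax / dt))
  }
  if (is.null(wavenumbers)) {
    fMHz <- seq_len(freqSamples) / freqSamples * 5   # (0, 5] MHz
    wavenumbers <- 2 * pi * fMHz / soundSpeed        # 1/mm (f in 1/us)
  }
  new("PATGeometry", numTransducers = as.integer(numTransducers),
      ringRadius = ringRadius, soundSpeed = soundSpeed,
      gridSide = as.integer(gridSide), gridExtent = gridExtent,
      timeSamples = as.integer(timeSamples), dt = dt,
      wavenumbers = wavenumbers)
}

#' @rdname patGeometry
#' @param ... overrides passed to [patGeometry()].
#' @export
deskGeometry <- function(...) {
  defaults <- list(numTransducers = 16L, ringRadius = 40, soundSpeed = 1.5,
                   gridSide = 16L, gridExtent = 50, dt = 0.25,
                   freqSamples = 8L)
  do.call(patGeometry, modifyList(defaults, list(...)))
}

# transducer positions (x, y) on the ring, equally spaced, first at angle 0
transducerPositions <- function(geom) {
  ang <- 2 * pi * (seq_len(geom@numTransducers) - 1) / geom@numTransducers
  cbind(x = geom@ringRadius * cos(ang), y = geom@ringRadius * sin(ang))
}

# pixel centres in mm, returned in row-major image order:
# row i (top, +y) varies slowest, column j (x) fastest
pixelCenters <- function(geom) {
  n <- geom@gridSide
  half <- geom@gridExtent / 2
  step <- geom@gridExtent / n
  xs <- -half + (seq_len(n) - 0.5) * step
  ys <- half - (seq_len(n) - 0.5) * step
  cbind(x = rep(xs, times = n), y = rep(ys, each = n))
}

#' Build a random Gaussian measurement matrix
#'
#' Draws an \eqn{M \times N^2} matrix with i.i.d. entries from
#' \eqn{N(0, 1/M)}, where \eqn{M = \mathrm{round}(ratio \cdot N^2)}.  The
#' \eqn{1/M} variance makes \eqn{E\|Kx\|^2 \approx \|x\|^2}, so the
#' restricted-isometry diagnostic reads on the natural scale.
#'
#' @param gridSide integer, image side \eqn{N}.
#' @param ratio numeric in (0, 1], undersampling ratio \eqn{M/N^2}.
#' @param seed integer.
#' @return a [MeasurementMatrix-class] of kind \code{"gaussian"}.
#' @export
gaussianMatrix <- function(gridSide, ratio, seed) {
  if (ratio <= 0 || ratio > 1)
    stop("invalid argument: ratio must lie in (0, 1]")
  n2 <- as.integer(gridSide)^2
  m <- as.integer(round(ratio * n2))
  if (m < 1) stop("invalid argument: ratio yields zero measurement rows")
  ent <- withSeed(seed, matrix(rnorm(m * n2, sd = 1 / sqrt(m)), m, n2))
  new("MeasurementMatrix", entries = ent, kind = "gaussian",
      gridSide = as.integer(gridSide), undersamplingRatio = m / n2,
      geometry = NULL, seed = as.integer(seed))
}

#' Build the time-domain PAT measurement matrix
#'
#' Discretises the spherical-delay kernel
#' \eqn{K(h,t)_{(i,j)} = \frac{1}{2\pi c}\,\delta(t - |r_{i,j} - r_h|/c)}
#' on the time grid \eqn{t = s\,\Delta t}, \eqn{s = 1,\dots,q_s}: row
#' \eqn{(h, s)} has the value \eqn{1/(2\pi c)} at column \eqn{(i,j)} iff
#' \eqn{|s\Delta t - |r_{i,j}-r_h|/c| \le \Delta t/2} (nearest-sample
#' assignment of the delta), else 0.  Rows are ordered with \eqn{h} outer
#' and \eqn{s} inner: row index \eqn{(h-1) q_s + s}.  Columns follow the
#' row-major image order used throughout the package.
#'
#' @param geometry a [PATGeometry-class].
#' @return a [MeasurementMatrix-class] of kind \code{"pat_time"}.
#' @export
patMatrixTime <- function(geometry) {
  stopifnot(is(geometry, "PATGeometry"))
  validObject(geometry)
  n <- geometry@gridSide
  qs <- geometry@timeSamples
  dt <- geometry@dt
  cc <- geometry@soundSpeed
  tp <- transducerPositions(geometry)
  px <- pixelCenters(geometry)
  if (any(sqrt(px[, 1]^2 + px[, 2]^2) >= geometry@ringRadius))
    stop("geometry error: pixel on or outside the transducer ring")
  p <- geometry@numTransducers
  ent <- matrix(0, p * qs, n * n)
  val <- 1 / (2 * pi * cc)
  for (h in seq_len(p)) {
    d <- sqrt((px[, 1] - tp[h, 1])^2 + (px[, 2] - tp[h, 2])^2)
    tt <- d / cc
    for (s in seq_len(qs)) {
      hit <- abs(s * dt - tt) <= dt / 2
      if (any(hit)) ent[(h - 1) * qs + s, hit] <- val
    }
  }
  n2 <- n * n
  new("MeasurementMatrix", entries = ent, kind = "pat_time",
      gridSide = n, undersamplingRatio = nrow(ent) / n2,
      geometry = geometry, seed = NA_integer_)
}

#' Build the frequency-domain PAT measurement matrix
#'
#' Complex kernel
#' \eqn{K(h,n)_{(i,j)} = i c k_n \exp(-i k_n |r_{i,j}-r_h|) / |r_{i,j}-r_h|},
#' so each entry has modulus \eqn{c k_n / |r_{i,j}-r_h|} and phase
#' \eqn{\pi/2 - k_n |r_{i,j}-r_h|} (mod \eqn{2\pi}).  Rows are ordered with
#' \eqn{h} outer and the wavenumber index \eqn{n} inner.
#'
#' @param geometry a [PATGeometry-class] with non-negative wavenumbers.
#' @return a [MeasurementMatrix-class] of kind \code{"pat_freq"}.
#' @export
patMatrixFreq <- function(geometry) {
  stopifnot(is(geometry, "PATGeometry"))
  validObject(geometry)
  n <- geometry@gridSide
  kn <- geometry@wavenumbers
  qn <- length(kn)
  cc <- geometry@soundSpeed
  tp <- transducerPositions(geometry)
  px <- pixelCenters(geometry)
  p <- geometry@numTransducers
  ent <- matrix(complex(real = 0), p * qn, n * n)
  for (h in seq_len(p)) {
    d <- sqrt((px[, 1] - tp[h, 1])^2 + (px[, 2] - tp[h, 2])^2)
    if (any(d <= 0)) stop("geometry error: zero pixel-transducer distance")
    for (nn in seq_len(qn)) {
      ent[(h - 1) * qn + nn, ] <-
        1i * cc * kn[nn] * exp(-1i * kn[nn] * d) / d
    }
  }
  n2 <- n * n
  new("MeasurementMatrix", entries = ent, kind = "pat_freq",
      gridSide = n, undersamplingRatio = nrow(ent) / n2,
      geometry = geometry, seed = NA_integer_)
}

#' Wrap an explicit matrix as a measurement operator
#'
#' Mainly for tests and for identity/custom operators; kind is inferred
#' from the storage mode unless given.
#'
#' @param m numeric or complex matrix with \code{gridSide^2} columns.
#' @param gridSide integer image side.
#' @param kind operator kind label.
#' @return a [MeasurementMatrix-class].
#' @export
asMeasurementMatrix <- function(m, gridSide,
                                kind = if (is.complex(m)) "pat_freq"
                                       else "gaussian") {
  new("MeasurementMatrix", entries = m, kind = kind,
      gridSide = as.integer(gridSide),
      undersamplingRatio = nrow(m) / as.integer(gridSide)^2,
      geometry = NULL, seed = NA_integer_)
}

#' Apply the forward measurement
#'
#' Computes \eqn{v = K\,\mathrm{vec}(x)} with row-major vectorisation,
#' optionally adding i.i.d. Gaussian noise of standard deviation
#' \code{noiseSigma} (added to real and imaginary parts independently for
#' complex operators).
#'
#' @param K a [MeasurementMatrix-class].
#' @param x a [Phantom-class] or numeric matrix of matching side.
#' @param noiseSigma numeric \eqn{\ge 0}.
#' @param seed optional integer seed for the noise draw.
#' @return a [MeasurementVector-class].
#' @name measure
#' @export
setMethod("measure", "MeasurementMatrix",
  function(K, x, noiseSigma = 0, seed = NULL) {
    m <- if (is(x, "Phantom")) x@pixels else x
    if (!is.matrix(m) || nrow(m) * ncol(m) != ncol(K@entries))
      stop("dimension error: image size does not match operator columns")
    v <- as.vector(K@entries %*% vecRowMajor(m))
    if (noiseSigma > 0) {
      addNoise <- function() {
        if (is.complex(v))
          v + complex(real = rnorm(length(v), sd = noiseSigma),
                      imaginary = rnorm(length(v), sd = noiseSigma))
        else v + rnorm(length(v), sd = noiseSigma)
      }
      v <- if (is.null(seed)) addNoise() else withSeed(seed, addNoise())
    }
    new("MeasurementVector", values = v, sourceMatrixId = K@kind,
        noiseSigma = noiseSigma)
  })

#' Transpose-proxy back-projection
#'
#' Computes the artifact-laden image proxy \eqn{\hat V = K^T v} (conjugate
#' transpose for complex operators, real part taken) and reshapes it to
#' \eqn{N \times N} in row-major order.  This is the fixed "fully
#' connected" stage feeding the reconstruction networks.
#'
#' @param K a [MeasurementMatrix-class].
#' @param v a [MeasurementVector-class] or plain vector of length \eqn{M}.
#' @return numeric \eqn{N \times N} matrix (not clamped, not normalised).
#' @name proxyImage
#' @export
setMethod("proxyImage", "MeasurementMatrix", function(K, v) {
  vv <- if (is(v, "MeasurementVector")) v@values else v
  if (length(vv) != nrow(K@entries))
    stop("dimension error: measurement length does not match operator rows")
  z <- as.vector(crossprod(Conj(K@entries), vv))
  unvecRowMajor(Re(z), K@gridSide)
})

#' Monte-Carlo restricted-isometry diagnostic
#'
#' Estimates how far an operator is from an isometry on \eqn{s}-sparse
#' vectors.  For each trial the protocol is, in order:
#' \code{support <- sample.int(ncol, s)}, \code{vals <- rnorm(s)},
#' \eqn{\theta} the unit vector with \code{vals/||vals||} on the support;
#' the ratio \eqn{\|K\theta\|^2/\|\theta\|^2} is computed as
#' \code{sum((K \%*\% theta)^2) / sum(theta^2)} on the full-length
#' \eqn{\theta} (the explicit quotient keeps exact isometries at ratio 1
#' bit-for-bit).  The report
#' contains the extreme ratios and
#' \eqn{\hat\delta = \max(1 - r_{min},\; r_{max} - 1)}.
#'
#' @param K a [MeasurementMatrix-class] (real entries).
#' @param sparsity integer \eqn{s}, \eqn{1 \le s \le N^2}.
#' @param trials integer \eqn{\ge 1}.
#' @param seed integer.
#' @return a [RIPReport-class].
#' @export
empiricalRIP <- function(K, sparsity, trials = 100L, seed = 1L) {
  ncols <- ncol(K@entries)
  if (sparsity < 1 || sparsity > ncols)
    stop("invalid argument: sparsity must lie in [1, N^2]")
  if (trials < 1) stop("invalid argument: trials must be >= 1")
  ent <- K@entries
  rmin <- Inf; rmax <- -Inf
  withSeed(seed, {
    for (i in seq_len(trials)) {
      supp <- sample.int(ncols, sparsity)
      vals <- rnorm(sparsity)
      theta <- numeric(ncols)
      theta[supp] <- vals / sqrt(sum(vals^2))
      z <- as.vector(ent %*% theta)
      ratio <- sum(z^2) / sum(theta^2)
      if (ratio < rmin) rmin <- ratio
      if (ratio > rmax) rmax <- ratio
    }
  })
  new("RIPReport", sparsity = as.integer(sparsity),
      trials = as.integer(trials),
      deltaHat = max(1 - rmin, rmax - 1),
      ratioMin = rmin, ratioMax = rmax)
}
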
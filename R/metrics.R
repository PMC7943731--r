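#' SSIM configuration
#'
#' Parameters of the structural-similarity index
#' \deqn{SSIM(x,y) = l(x,y)^a \, c(x,y)^b \, s(x,y)^\gamma}
#' with luminance \eqn{l = (2\mu_x\mu_y + c_1)/(\mu_x^2 + \mu_y^2 + c_1)},
#' contrast \eqn{c = (2\sigma_x\sigma_y + c_2)/(\sigma_x^2 + \sigma_y^2 +
#' c_2)} and structure \eqn{s = (\sigma_{xy} + c_3)/(\sigma_x\sigma_y +
#' c_3)}, where \eqn{c_1 = (k_1 L)^2}, \eqn{c_2 = (k_2 L)^2} and by default
#' \eqn{c_3 = c_2/2} (which collapses the product to the familiar
#' two-factor form when \eqn{b = \gamma}).  \code{window = "global"}
#' computes the moments once over the whole image; \code{"gaussian"}
#' averages a local SSIM map computed with a Gaussian window (default
#' 11x11, sigma 1.5) over the valid (fully-overlapping) region.
#'
#' Variances and covariance use the population (\eqn{1/n}) convention.
#' \eqn{L} defaults to 2, the data range of \eqn{[-1, 1]}-normalised
#' images.
#'
#' @param a,b,gamma positive exponents.
#' @param k1,k2 small positive stabilising constants.
#' @param dataRange positive real \eqn{L}.
#' @param window \code{"gaussian"} or \code{"global"}.
#' @param windowSize odd integer, Gaussian window side.
#' @param windowSigma positive real.
#' @param c3 stabiliser of the structure term; default \eqn{c_2/2}.
#' @return a list of validated settings.
#' @export
ssimConfig <- function(a = 1, b = 1, gamma = 1, k1 = 0.01, k2 = 0.03,
                       dataRange = 2, window = c("gaussian", "global"),
                       windowSize = 11L, windowSigma = 1.5, c3 = NULL) {
  window <- match.arg(window)
  stopifnot(a > 0, b > 0, gamma > 0, k1 > 0, k2 > 0, dataRange > 0,
            windowSize %% 2 == 1, windowSigma > 0)
  c1 <- (k1 * dataRange)^2
  c2 <- (k2 * dataRange)^2
  if (is.null(c3)) c3 <- c2 / 2
  stopifnot(c1 > 0, c2 > 0, c3 > 0)
  list(a = a, b = b, gamma = gamma, k1 = k1, k2 = k2,
       dataRange = dataRange, window = window,
       windowSize = as.integer(windowSize), windowSigma = windowSigma,
       c1 = c1, c2 = c2, c3 = c3)
}

# signed power: keeps the sign of t for non-integer exponents (the
# structure term can be negative)
signedPow <- function(t, e) sign(t) * abs(t)^e

# local moments of x under weights w (a normalised kernel), valid region
localMoments <- function(x, w) {
  k <- nrow(w)
  n <- nrow(x); m <- ncol(x)
  on <- n - k + 1; om <- m - k + 1
  out <- matrix(0, on, om)
  for (dy in seq_len(k)) {
    for (dx in seq_len(k)) {
      if (w[dy, dx] == 0) next
      out <- out + w[dy, dx] * x[dy:(dy + on - 1), dx:(dx + om - 1)]
    }
  }
  out
}

gaussianKernel <- function(size, sigma) {
  h <- (size - 1) / 2
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# SSIM term maps (or scalars for the global window)
ssimTerms <- function(x, y, cfg) {
  if (cfg$window == "global") {
    mx <- mean(x); my <- mean(y)
    vx <- mean(x * x) - mx * mx
    vy <- mean(y * y) - my * my
    cxy <- mean(x * y) - mx * my
  } else {
    w <- gaussianKernel(cfg$windowSize, cfg$windowSigma)
    if (nrow(x) < cfg$windowSize)
      stop("image smaller than the SSIM window; use window = 'global'")
    mx <- localMoments(x, w); my <- localMoments(y, w)
    vx <- localMoments(x * x, w) - mx * mx
    vy <- localMoments(y * y, w) - my * my
    cxy <- localMoments(x * y, w) - mx * my
  }
  # raw (possibly minutely negative from cancellation) variances are kept
  # for the ratio terms so that identical inputs give exactly 1; the
  # square roots are floored at zero
  sx <- sqrt(pmax(vx, 0)); sy <- sqrt(pmax(vy, 0))
  list(
    l = (2 * mx * my + cfg$c1) / (mx * mx + my * my + cfg$c1),
    c = (2 * sx * sy + cfg$c2) / (vx + vy + cfg$c2),
    s = (cxy + cfg$c3) / (sx * sy + cfg$c3),
    # collapsed contrast-structure factor, exact when c3 = c2/2
    cs = (2 * cxy + cfg$c2) / (vx + vy + cfg$c2)
  )
}

#' Structural similarity index
#'
#' Computes SSIM from first principles (see [ssimConfig()]).  When
#' \eqn{b = \gamma} and \eqn{c_3 = c_2/2} the contrast and structure terms
#' are combined algebraically into the numerically stable two-factor form,
#' which makes \code{ssim(x, x)} exactly 1; otherwise the three terms are
#' evaluated separately with sign-preserving powers.
#'
#' @param x,y [Phantom-class] objects or numeric matrices of equal shape.
#' @param cfg configuration from [ssimConfig()].
#' @return numeric scalar in \eqn{[-1, 1]}.
#' @export
ssim <- function(x, y, cfg = ssimConfig()) {
  xm <- if (is(x, "Phantom")) x@pixels else x
  ym <- if (is(y, "Phantom")) y@pixels else y
  if (!identical(dim(xm), dim(ym)))
    stop("dimension error: images must have the same shape")
  tm <- ssimTerms(xm, ym, cfg)
  collapsed <- (cfg$b == cfg$gamma) && (cfg$c3 == cfg$c2 / 2)
  v <- if (collapsed)
    signedPow(tm$l, cfg$a) * signedPow(tm$cs, cfg$b)
  else
    signedPow(tm$l, cfg$a) * signedPow(tm$c, cfg$b) *
      signedPow(tm$s, cfg$gamma)
  mean(v)
}

#' Peak signal-to-noise ratio
#'
#' \deqn{PSNR = 10 \log_{10}(peak^2 / MSE)} in decibels, where MSE is the
#' mean squared pixel difference.  Identical images have MSE 0 and return
#' the \code{Inf} sentinel (never silently capped).  \code{peak} defaults
#' to the data range 2 of \eqn{[-1,1]}-normalised images; pass
#' \code{peak = "image"} to use the maximum absolute value of \code{x}.
#'
#' @param x,y [Phantom-class] objects or numeric matrices of equal shape.
#' @param peak positive real, or \code{"image"}.
#' @return numeric scalar in dB (possibly \code{Inf}).
#' @export
psnr <- function(x, y, peak = 2) {
  xm <- if (is(x, "Phantom")) x@pixels else x
  ym <- if (is(y, "Phantom")) y@pixels else y
  if (!identical(dim(xm), dim(ym)))
    stop("dimension error: images must have the same shape")
  if (identical(peak, "image")) peak <- max(abs(xm))
  if (!is.numeric(peak) || peak <= 0) stop("peak must be positive")
  mse <- mean((xm - ym)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Build a per-image metric record table
#'
#' @param imageId character vector.
#' @param method character vector.
#' @param ratio numeric vector of undersampling ratios.
#' @param ssim,psnrDb numeric vectors.
#' @return data.frame with one row per image.
#' @export
metricRecord <- function(imageId, method, ratio, ssim, psnrDb) {
  data.frame(imageId = imageId, method = method, ratio = ratio,
             ssim = ssim, psnrDb = psnrDb, stringsAsFactors = FALSE)
}

#' Aggregate per-image metrics into a mean +/- SD report
#'
#' Groups records by (method, ratio) and reports the arithmetic mean and
#' sample standard deviation (\eqn{n-1} denominator; 0 when \eqn{n = 1})
#' of SSIM and PSNR.  Infinite PSNR sentinels are excluded from the PSNR
#' aggregation; their count is reported in \code{nInfPsnr}.
#'
#' @param records data.frame as produced by [metricRecord()].
#' @return data.frame keyed by (method, ratio) with columns
#'   \code{meanSsim}, \code{sdSsim}, \code{meanPsnr}, \code{sdPsnr},
#'   \code{n}, \code{nInfPsnr}.
#' @export
aggregateMetrics <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("invalid argument: records must be a non-empty data.frame")
  key <- interaction(records$method, records$ratio, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    fin <- is.finite(g$psnrDb)
    sd0 <- function(v) if (length(v) <= 1) 0 else sd(v)
    data.frame(
      method = g$method[1], ratio = g$ratio[1],
      meanSsim = mean(g$ssim), sdSsim = sd0(g$ssim),
      meanPsnr = if (any(fin)) mean(g$psnrDb[fin]) else NA_real_,
      sdPsnr = if (any(fin)) sd0(g$psnrDb[fin]) else NA_real_,
      n = nrow(g), nInfPsnr = sum(!fin),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$method, -out$ratio), , drop = FALSE]
}
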
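#' Total variation of an image
#'
#' Forward-difference total variation.  With differences
#' \eqn{d^v_{i,j} = x_{i+1,j} - x_{i,j}} and
#' \eqn{d^h_{i,j} = x_{i,j+1} - x_{i,j}} (differences across the image
#' border are zero, i.e. replicate boundary):
#' \itemize{
#'   \item anisotropic: \eqn{\sum |d^v| + \sum |d^h|};
#'   \item isotropic: \eqn{\sum_{i,j} \sqrt{(d^v_{i,j})^2 +
#'     (d^h_{i,j})^2}}.
#' }
#'
#' @param x [Phantom-class] or numeric matrix.
#' @param flavor \code{"anisotropic"} (default) or \code{"isotropic"}.
#' @return numeric scalar \eqn{\ge 0}.
#' @export
totalVariation <- function(x, flavor = c("anisotropic", "isotropic")) {
  flavor <- match.arg(flavor)
  m <- if (is(x, "Phantom")) x@pixels else x
  stopifnot(is.matrix(m))
  n <- nrow(m); p <- ncol(m)
  dv <- rbind(m[-1, , drop = FALSE] - m[-n, , drop = FALSE],
              matrix(0, 1, p))
  dh <- cbind(m[, -1, drop = FALSE] - m[, -p, drop = FALSE],
              matrix(0, n, 1))
  if (flavor == "anisotropic") sum(abs(dv)) + sum(abs(dh))
  else sum(sqrt(dv^2 + dh^2))
}

# gradient operator (forward differences, zero across the border) and its
# negative adjoint (divergence), used by the dual TV prox
tvGrad <- function(m) {
  n <- nrow(m); p <- ncol(m)
  dv <- rbind(m[-1, , drop = FALSE] - m[-n, , drop = FALSE],
              matrix(0, 1, p))
  dh <- cbind(m[, -1, drop = FALSE] - m[, -p, drop = FALSE],
              matrix(0, n, 1))
  list(dv = dv, dh = dh)
}

tvDiv <- function(dv, dh) {
  n <- nrow(dv); p <- ncol(dv)
  out <- matrix(0, n, p)
  out[1, ] <- out[1, ] - dv[1, ]
  out[2:n, ] <- out[2:n, ] - dv[2:n, ] + dv[1:(n - 1), ]
  out[, 1] <- out[, 1] - dh[, 1]
  out[, 2:p] <- out[, 2:p] - dh[, 2:p] + dh[, 1:(p - 1)]
  -out
}

# proximal operator of lambda * TV via the dual fast gradient projection
# scheme (Beck & Teboulle): solves min_u 0.5||u - z||^2 + lambda TV(u)
tvProx <- function(z, lambda, flavor = "anisotropic", iters = 40L) {
  if (lambda <= 0) return(z)
  n <- nrow(z); p <- ncol(z)
  pv <- matrix(0, n, p); ph <- matrix(0, n, p)
  rv <- pv; rh <- ph
  tk <- 1
  L <- 8  # Lipschitz constant of the dual gradient
  for (it in seq_len(iters)) {
    u <- z - lambda * tvDiv(rv, rh)
    g <- tvGrad(u)
    # dual gradient of 0.5 * ||z - lambda * div(p)||^2 is +lambda*grad(u)
    # under the div = -grad^T convention, hence the descent step subtracts
    qv <- rv - g$dv / (L * lambda)
    qh <- rh - g$dh / (L * lambda)
    if (flavor == "anisotropic") {
      nv <- clamp(qv, -1, 1); nh <- clamp(qh, -1, 1)
    } else {
      mag <- pmax(1, sqrt(qv^2 + qh^2))
      nv <- qv / mag; nh <- qh / mag
    }
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    rv <- nv + (tk - 1) / tk1 * (nv - pv)
    rh <- nh + (tk - 1) / tk1 * (nh - ph)
    pv <- nv; ph <- nh
    tk <- tk1
  }
  z - lambda * tvDiv(pv, ph)
}

#' Total-variation-regularised reconstruction
#'
#' Approximately minimises
#' \deqn{F(x) = \tfrac12 \|Kx - v\|^2 + \lambda\,TV(x)}
#' with a monotone accelerated proximal-gradient scheme (monotone FISTA):
#' a gradient step on the quadratic data term with backtracking line
#' search, followed by an inner dual TV-proximal solve.  The monotone
#' variant keeps the best iterate, so the recorded objective trace is
#' non-increasing.  Iteration stops at \code{maxIters} or when the
#' relative objective change drops below \code{tol}.
#'
#' @param K a [MeasurementMatrix-class] (real entries).
#' @param v a [MeasurementVector-class] or numeric vector.
#' @param lambda positive regularisation weight; the packaged default 0.002
#'   was fixed once by a grid search on the bundled piecewise-constant
#'   fixture phantom at undersampling ratio 0.5.
#' @param maxIters integer \eqn{\ge 1}.
#' @param tol positive relative-change stopping tolerance.
#' @param flavor TV flavour, \code{"anisotropic"} (default) or
#'   \code{"isotropic"}.
#' @param proxIters inner iterations of the dual TV prox.
#' @param x0 optional starting image (matrix); default zero.
#' @return a [TVSolution-class].
#' @export
tvMinimize <- function(K, v, lambda = 0.002, maxIters = 200L, tol = 1e-7,
                       flavor = c("anisotropic", "isotropic"),
                       proxIters = 40L, x0 = NULL) {
  flavor <- match.arg(flavor)
  stopifnot(is(K, "MeasurementMatrix"))
  vv <- if (is(v, "MeasurementVector")) v@values else v
  if (!all(is.finite(vv))) stop("invalid input: non-finite measurement data")
  if (lambda <= 0) stop("lambda must be positive")
  if (maxIters < 1) stop("maxIters must be >= 1")
  ent <- K@entries
  n <- K@gridSide
  obj <- function(xm) {
    r <- as.vector(ent %*% vecRowMajor(xm)) - vv
    0.5 * sum(r^2) + lambda * totalVariation(xm, flavor)
  }
  gradData <- function(xm) {
    r <- as.vector(ent %*% vecRowMajor(xm)) - vv
    list(g = unvecRowMajor(as.vector(crossprod(ent, r)), n),
         f = 0.5 * sum(r^2))
  }
  x <- if (is.null(x0)) matrix(0, n, n) else x0
  y <- x
  tk <- 1
  # Lipschitz estimate ||K||^2 by deterministic power iteration; any
  # underestimate is corrected by the backtracking loop below
  zn <- vecRowMajor(matrix(1, n, n) + diag(1e-3, n))
  zn <- zn / sqrt(sum(zn^2))
  for (i in 1:20) {
    zn <- as.vector(crossprod(ent, ent %*% zn))
    zn <- zn / sqrt(sum(zn^2))
  }
  L <- max(sum((as.vector(ent %*% zn))^2), 1e-12)  # Rayleigh quotient
  trace <- obj(x)
  bestF <- trace
  diverge <- 0L
  stall <- 0L
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxIters)) {
    gd <- gradData(y)
    # backtracking on the data-term majorisation at y
    repeat {
      z <- tvProx(y - gd$g / L, lambda / L, flavor, proxIters)
      r <- as.vector(ent %*% vecRowMajor(z)) - vv
      fz <- 0.5 * sum(r^2)
      quad <- gd$f + sum(gd$g * (z - y)) + 0.5 * L * sum((z - y)^2)
      if (fz <= quad + 1e-12 * abs(quad)) break
      L <- 2 * L
    }
    Fz <- fz + lambda * totalVariation(z, flavor)
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    if (Fz <= bestF) {
      xNew <- z
      FNew <- Fz
    } else {
      xNew <- x            # monotone step: keep the incumbent
      FNew <- bestF
    }
    y <- xNew + tk / tk1 * (z - xNew) + (tk - 1) / tk1 * (xNew - x)
    x <- xNew
    prevF <- bestF
    bestF <- FNew
    trace <- c(trace, bestF)
    if (Fz > prevF * (1 + 1e-9) + 1e-9) diverge <- diverge + 1L
    else diverge <- 0L
    if (diverge >= 10L)
      stop("solver failure: objective increased for 10 consecutive ",
           "iterations")
    # declare convergence after three consecutive near-zero relative
    # objective changes (a single stalled accelerated step is not enough)
    if ((prevF - bestF) <= tol * max(abs(prevF), 1e-12))
      stall <- stall + 1L
    else stall <- 0L
    if (stall >= 3L) {
      converged <- TRUE
      break
    }
    tk <- tk1
  }
  new("TVSolution",
      image = new("Phantom", pixels = x, label = "tv-minimization"),
      objectiveTrace = trace, iterationsRun = as.integer(it),
      converged = converged)
}
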
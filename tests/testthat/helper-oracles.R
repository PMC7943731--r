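# Independent brute-force oracles used to check the implementation.
# These deliberately avoid the package's own code paths: explicit loops,
# direct scalar formulas, exhaustive enumeration.

# Count connected components of (mat > threshold) by flood fill
# (8-connectivity), with an explicit stack.
floodFillComponents <- function(mat, threshold = 0) {
  n <- nrow(mat); m <- ncol(mat)
  seen <- matrix(FALSE, n, m)
  comp <- 0L
  for (i0 in seq_len(n)) {
    for (j0 in seq_len(m)) {
      if (seen[i0, j0] || mat[i0, j0] <= threshold) next
      comp <- comp + 1L
      stack <- list(c(i0, j0))
      seen[i0, j0] <- TRUE
      while (length(stack) > 0) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (di in -1:1) for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          i <- cur[1] + di; j <- cur[2] + dj
          if (i < 1 || i > n || j < 1 || j > m) next
          if (seen[i, j] || mat[i, j] <= threshold) next
          seen[i, j] <- TRUE
          stack[[length(stack) + 1]] <- c(i, j)
        }
      }
    }
  }
  comp
}

# 90-degree counter-clockwise rotation as an explicit index permutation:
# output[i, j] = input[j, n + 1 - i]
rot90Oracle <- function(m, quarterTurns = 1) {
  out <- m
  for (q in seq_len(quarterTurns %% 4)) {
    n <- nrow(out); p <- ncol(out)
    res <- matrix(0, p, n)
    for (i in seq_len(p)) for (j in seq_len(n))
      res[i, j] <- out[j, p + 1 - i]
    out <- res
  }
  out
}

# scalar three-term SSIM (global window): direct evaluation of the
# luminance, contrast and structure factors with population moments
ssimOracle <- function(x, y, a = 1, b = 1, gamma = 1, k1 = 0.01,
                       k2 = 0.03, L = 2) {
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2; c3 <- c2 / 2
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  sx <- sqrt(vx); sy <- sqrt(vy)
  l <- (2 * mx * my + c1) / (mx^2 + my^2 + c1)
  cc <- (2 * sx * sy + c2) / (vx + vy + c2)
  ss <- (cxy + c3) / (sx * sy + c3)
  sign(l) * abs(l)^a * sign(cc) * abs(cc)^b * sign(ss) * abs(ss)^gamma
}

# PSNR via an explicit double loop over pixels
psnrOracle <- function(x, y, peak = 2) {
  acc <- 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x)))
    acc <- acc + (x[i, j] - y[i, j])^2
  mse <- acc / (nrow(x) * ncol(x))
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# Monte-Carlo RIP diagnostic re-implemented from its documented protocol:
# per trial, sample.int for the support, rnorm for the values, unit
# normalisation, full K %*% theta, quotient of sums of squares.
ripOracle <- function(ent, s, trials, seed) {
  rmin <- Inf; rmax <- -Inf
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  for (i in seq_len(trials)) {
    supp <- sample.int(ncol(ent), s)
    vals <- rnorm(s)
    theta <- numeric(ncol(ent))
    theta[supp] <- vals / sqrt(sum(vals^2))
    z <- as.vector(ent %*% theta)
    ratio <- sum(z^2) / sum(theta^2)
    rmin <- min(rmin, ratio); rmax <- max(rmax, ratio)
  }
  list(ratioMin = rmin, ratioMax = rmax,
       deltaHat = max(1 - rmin, rmax - 1))
}

# exhaustive enumeration of the time-domain PAT kernel: for every row
# (h, s) and pixel (i, j), fire iff |s*dt - d/c| <= dt/2
patTimeOracle <- function(geom) {
  n <- geom@gridSide
  p <- geom@numTransducers
  qs <- geom@timeSamples
  dt <- geom@dt; cc <- geom@soundSpeed
  ang <- 2 * pi * (seq_len(p) - 1) / p
  tx <- geom@ringRadius * cos(ang); ty <- geom@ringRadius * sin(ang)
  half <- geom@gridExtent / 2; step <- geom@gridExtent / n
  out <- matrix(0, p * qs, n * n)
  for (h in seq_len(p)) {
    for (i in seq_len(n)) {      # image row (y from top)
      for (j in seq_len(n)) {    # image column (x)
        px <- -half + (j - 0.5) * step
        py <- half - (i - 0.5) * step
        d <- sqrt((px - tx[h])^2 + (py - ty[h])^2)
        col <- (i - 1) * n + j
        for (s in seq_len(qs)) {
          if (abs(s * dt - d / cc) <= dt / 2)
            out[(h - 1) * qs + s, col] <- 1 / (2 * pi * cc)
        }
      }
    }
  }
  out
}

# small helpers shared by tests
randomImage <- function(n, seed) {
  set.seed(seed)
  matrix(runif(n * n, -1, 1), n, n)
}

expectPhantomRange <- function(p) {
  testthat::expect_true(all(PATRecon::pixels(p) >= -1) &&
                          all(PATRecon::pixels(p) <= 1))
}
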
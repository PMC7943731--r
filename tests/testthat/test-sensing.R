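test_that("gaussian matrices have the documented shape and moments", {
  K <- gaussianMatrix(8, 0.5, seed = 1)
  expect_identical(dim(entries(K)), c(32L, 64L))
  expect_equal(undersamplingRatio(K), 0.5)
  K1 <- gaussianMatrix(8, 1.0, seed = 1)
  expect_identical(dim(entries(K1)), c(64L, 64L))
  # moment oracle: mean within 3 standard errors, variance within 10%
  K2 <- gaussianMatrix(16, 0.3, seed = 5)
  e <- entries(K2)
  m <- nrow(e)
  expect_lt(abs(mean(e)), 3 / (m * 16))
  expect_lt(abs(var(as.vector(e)) - 1 / m) / (1 / m), 0.1)
  # reproducible, and ratio recomputes exactly
  expect_identical(entries(gaussianMatrix(16, 0.3, seed = 5)), e)
  expect_equal(undersamplingRatio(K2), m / 256)
  expect_error(gaussianMatrix(8, 0, seed = 1), "invalid argument")
  expect_error(gaussianMatrix(8, 1.5, seed = 1), "invalid argument")
})

test_that("time-domain PAT kernel matches exhaustive distance binning", {
  geom <- deskGeometry(gridSide = 16L, numTransducers = 8L,
                       timeSamples = 120L)
  K <- patMatrixTime(geom)
  expect_identical(matrixKind(K), "pat_time")
  oracle <- patTimeOracle(geom)
  expect_identical(dim(entries(K)), dim(oracle))
  expect_equal(entries(K), oracle, tolerance = 1e-14)
  # nonzero entries all equal 1/(2*pi*c); per-row counts match the oracle
  nz <- entries(K)[entries(K) != 0]
  expect_true(all(abs(nz - 1 / (2 * pi * geom@soundSpeed)) < 1e-15))
  expect_identical(rowSums(entries(K) != 0), rowSums(oracle != 0))
})

test_that("a too-short time axis yields an all-zero delay matrix", {
  # travel times exceed qs*dt for every pixel, so the delta never fires
  geom <- deskGeometry(gridSide = 16L, numTransducers = 4L,
                       timeSamples = 5L, dt = 0.25)
  K <- patMatrixTime(geom)
  expect_true(all(entries(K) == 0))
})

test_that("frequency-domain PAT kernel has the closed-form entries", {
  geom <- deskGeometry(gridSide = 8L, numTransducers = 4L,
                       wavenumbers = c(0, 0.8, 2.1))
  K <- patMatrixFreq(geom)
  expect_identical(matrixKind(K), "pat_freq")
  expect_true(is.complex(entries(K)))
  # k = 0 rows vanish
  qn <- 3
  for (h in 1:4) expect_true(all(entries(K)[(h - 1) * qn + 1, ] == 0))
  # element-wise modulus and phase against direct evaluation
  ang <- 2 * pi * (0:3) / 4
  tx <- geom@ringRadius * cos(ang); ty <- geom@ringRadius * sin(ang)
  half <- geom@gridExtent / 2; step <- geom@gridExtent / 8
  cc <- geom@soundSpeed
  for (h in c(1L, 3L)) {
    for (nn in 2:3) {
      kn <- geom@wavenumbers[nn]
      row <- entries(K)[(h - 1) * qn + nn, ]
      for (col in c(1L, 13L, 40L, 64L)) {
        i <- (col - 1) %/% 8 + 1; j <- (col - 1) %% 8 + 1
        px <- -half + (j - 0.5) * step
        py <- half - (i - 0.5) * step
        d <- sqrt((px - tx[h])^2 + (py - ty[h])^2)
        expect_equal(Mod(row[col]), cc * kn / d, tolerance = 1e-12)
        expected <- 1i * cc * kn * exp(-1i * kn * d) / d
        expect_equal(row[col], expected, tolerance = 1e-12)
        # phase pi/2 - kn*d (mod 2pi)
        dphi <- (Arg(row[col]) - (pi / 2 - kn * d)) %% (2 * pi)
        expect_true(min(dphi, 2 * pi - dphi) < 1e-10)
      }
    }
  }
})

test_that("measurement is linear and matches direct multiplication", {
  n <- 8
  K <- gaussianMatrix(n, 0.5, seed = 2)
  zero <- matrix(0, n, n)
  expect_true(all(measure(K, zero)@values == 0))
  # identity operator returns the row-major vectorisation
  I <- asMeasurementMatrix(diag(n * n), n)
  x <- randomImage(n, seed = 4)
  expect_equal(measure(I, x)@values, as.vector(t(x)))
  # linearity on random pairs
  for (s in 1:10) {
    x1 <- randomImage(n, seed = 100 + s)
    x2 <- randomImage(n, seed = 200 + s)
    a <- 1.3; b <- -0.7
    lhs <- measure(K, a * x1 + b * x2)@values
    rhs <- a * measure(K, x1)@values + b * measure(K, x2)@values
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
  expect_error(measure(K, matrix(0, 4, 4)), "dimension error")
})

test_that("proxy is the adjoint of measure for all operator kinds", {
  geom <- deskGeometry(gridSide = 8L, numTransducers = 6L,
                       timeSamples = 40L)
  ops <- list(
    gaussian = gaussianMatrix(8, 0.4, seed = 3),
    pat_time = patMatrixTime(geom),
    pat_freq = patMatrixFreq(deskGeometry(gridSide = 8L,
                                          numTransducers = 6L))
  )
  for (nm in names(ops)) {
    K <- ops[[nm]]
    for (s in 1:10) {
      x <- randomImage(8, seed = 300 + s)
      set.seed(400 + s)
      v <- if (is.complex(entries(K)))
        complex(real = rnorm(nrow(entries(K))),
                imaginary = rnorm(nrow(entries(K))))
      else rnorm(nrow(entries(K)))
      # <Kx, v> = <vec(x), K^H v> with the real part on both sides
      lhs <- Re(sum(Conj(measure(K, x)@values) * v))
      rhs <- sum(as.vector(t(x)) *
                   as.vector(Re(crossprod(Conj(entries(K)), v))))
      denom <- max(abs(lhs), abs(rhs), 1e-10)
      expect_lt(abs(lhs - rhs) / denom, 1e-8,
                label = sprintf("adjoint identity for %s", nm))
      # and proxyImage is exactly that back-projection, reshaped
      expect_equal(as.vector(t(proxyImage(K, v))),
                   as.vector(Re(crossprod(Conj(entries(K)), v))),
                   tolerance = 1e-12)
    }
  }
  # identity operator: proxy inverts measure exactly
  I <- asMeasurementMatrix(diag(64), 8)
  x <- randomImage(8, seed = 9)
  expect_equal(proxyImage(I, measure(I, x)), x)
  expect_true(all(proxyImage(I, rep(0, 64)) == 0))
})

test_that("empirical RIP diagnostic matches its brute-force oracle", {
  I <- asMeasurementMatrix(diag(64), 8)
  r <- empiricalRIP(I, sparsity = 5, trials = 20, seed = 1)
  expect_identical(r@deltaHat, 0)
  r2 <- empiricalRIP(asMeasurementMatrix(2 * diag(64), 8), 5, 20, seed = 1)
  expect_equal(r2@ratioMin, 4)
  expect_equal(r2@ratioMax, 4)
  expect_equal(r2@deltaHat, 3)
  # gaussian case, bit-for-bit against the documented sampling protocol
  K <- gaussianMatrix(16, 0.5, seed = 3)   # M = 128, N^2 = 256
  got <- empiricalRIP(K, sparsity = 5, trials = 1000, seed = 3)
  want <- ripOracle(entries(K), 5, 1000, seed = 3)
  expect_identical(got@ratioMin, want$ratioMin)
  expect_identical(got@ratioMax, want$ratioMax)
  expect_identical(got@deltaHat, want$deltaHat)
  expect_error(empiricalRIP(K, sparsity = 300, trials = 5, seed = 1),
               "invalid argument")
})

test_that("measurement noise is seeded and sized correctly", {
  n <- 16
  K <- gaussianMatrix(n, 0.5, seed = 6)
  x <- randomImage(n, seed = 7)
  clean <- measure(K, x)
  noisy1 <- measure(K, x, noiseSigma = 0.1, seed = 11)
  noisy2 <- measure(K, x, noiseSigma = 0.1, seed = 11)
  expect_identical(noisy1@values, noisy2@values)
  resid <- noisy1@values - clean@values
  expect_gt(sd(resid), 0.05)
  expect_lt(sd(resid), 0.2)
  expect_equal(noisy1@noiseSigma, 0.1)
})
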
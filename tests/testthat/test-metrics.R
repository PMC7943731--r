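test_that("global-window SSIM matches the scalar three-term oracle", {
  cfg <- ssimConfig(window = "global")
  for (s in 1:100) {
    x <- randomImage(8, seed = 1000 + s)
    y <- randomImage(8, seed = 2000 + s)
    expect_equal(ssim(x, y, cfg), ssimOracle(x, y), tolerance = 1e-10)
  }
  # non-default exponents agree with the oracle too
  cfgE <- ssimConfig(a = 2, b = 1.5, gamma = 0.5, window = "global")
  x <- randomImage(8, seed = 42); y <- randomImage(8, seed = 43)
  expect_equal(ssim(x, y, cfgE),
               ssimOracle(x, y, a = 2, b = 1.5, gamma = 0.5),
               tolerance = 1e-10)
})

test_that("SSIM identities: self-similarity, symmetry, constant images", {
  x <- randomImage(16, seed = 5)
  for (w in c("global", "gaussian")) {
    cfg <- ssimConfig(window = w)
    expect_identical(ssim(x, x, cfg), 1)
    expect_equal(ssim(x, 0.5 * x, cfg), ssim(0.5 * x, x, cfg))
  }
  # constant images: contrast/structure degenerate to 1 via the
  # stabilising constants, leaving the luminance term alone
  a <- matrix(0.2, 8, 8); b <- matrix(0.6, 8, 8)
  cfg <- ssimConfig(window = "global")
  c1 <- (0.01 * 2)^2
  l <- (2 * 0.2 * 0.6 + c1) / (0.2^2 + 0.6^2 + c1)
  expect_equal(ssim(a, b, cfg), l, tolerance = 1e-12)
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 5, 5)), "dimension error")
})

test_that("SSIM is bounded and strictly penalises any perturbation", {
  cfg <- ssimConfig(window = "global")
  for (s in 1:25) {
    x <- randomImage(8, seed = 3000 + s)
    y <- randomImage(8, seed = 4000 + s)
    v <- ssim(x, y, cfg)
    expect_gte(v, -1); expect_lte(v, 1)
  }
  x <- randomImage(12, seed = 77)
  for (s in 1:5) {
    y <- x
    idx <- c(1, 40, 77, 100, 144)[s]
    y[idx] <- y[idx] + 0.25
    expect_lt(ssim(x, y, cfg), 1)
  }
})

test_that("three-term SSIM collapses to the two-factor form when c3 = c2/2", {
  x <- randomImage(16, seed = 8)
  y <- x + randomImage(16, seed = 9) * 0.2
  for (w in c("global", "gaussian")) {
    cfg <- ssimConfig(window = w)
    tm <- PATRecon:::ssimTerms(if (w == "global") x else x,
                               if (w == "global") y else y, cfg)
    expect_equal(mean(tm$l * tm$c * tm$s), mean(tm$l * tm$cs),
                 tolerance = 1e-12)
  }
})

test_that("PSNR matches the double-loop oracle and its exact identities", {
  expect_identical(psnr(randomImage(8, 1), randomImage(8, 1)), Inf)
  # MSE equal to peak^2 gives exactly 0 dB
  x <- matrix(-1, 8, 8); y <- matrix(1, 8, 8)
  expect_equal(psnr(x, y, peak = 2), 0)
  for (s in 1:100) {
    x <- randomImage(8, seed = 5000 + s)
    y <- randomImage(8, seed = 6000 + s)
    expect_equal(psnr(x, y, peak = 2), psnrOracle(x, y, peak = 2),
                 tolerance = 1e-10)
  }
  # per-image peak option
  x <- randomImage(8, seed = 3) * 0.5
  y <- randomImage(8, seed = 4) * 0.5
  expect_equal(psnr(x, y, peak = "image"),
               10 * log10(max(abs(x))^2 / mean((x - y)^2)))
  expect_error(psnr(matrix(0, 4, 4), matrix(0, 4, 5)), "dimension error")
})

test_that("PSNR decreases monotonically with added noise", {
  x <- pixels(generatePhantom(32, 2, seed = 3))
  vals <- vapply(c(0.01, 0.05, 0.1), function(sg) {
    set.seed(99)
    psnr(x, x + matrix(rnorm(length(x), sd = sg), nrow(x), ncol(x)))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("metric aggregation reproduces hand-computed mean and SD", {
  one <- metricRecord("a", "unet", 0.5, 0.9, 20)
  agg1 <- aggregateMetrics(one)
  expect_equal(agg1$meanSsim, 0.9)
  expect_equal(agg1$sdSsim, 0)
  expect_equal(agg1$meanPsnr, 20)
  expect_equal(agg1$sdPsnr, 0)
  expect_equal(agg1$n, 1L)
  two <- metricRecord(c("a", "b"), "unet", 0.5, c(0.8, 1.0), c(18, 22))
  agg2 <- aggregateMetrics(two)
  expect_equal(agg2$meanSsim, 0.9)
  expect_equal(agg2$sdSsim, sqrt(0.02), tolerance = 1e-12)
  # infinite PSNR sentinels are excluded but counted
  three <- metricRecord(c("a", "b", "c"), "unet", 0.5,
                        c(0.8, 1.0, 0.9), c(18, 22, Inf))
  agg3 <- aggregateMetrics(three)
  expect_equal(agg3$meanPsnr, 20)
  expect_equal(agg3$nInfPsnr, 1L)
  expect_equal(agg3$n, 3L)
  expect_error(aggregateMetrics(two[0, ]), "invalid argument")
})

test_that("aggregation groups by method and undersampling ratio", {
  ratios <- c(0.5, 0.3, 0.1, 0.05)
  rec <- do.call(rbind, lapply(ratios, function(r)
    metricRecord(c("a", "b"), "resunet", r, c(0.9, 0.92), c(25, 26))))
  rec <- rbind(rec, metricRecord("a", "tvmin", 0.5, 0.7, 16))
  agg <- aggregateMetrics(rec)
  expect_equal(nrow(agg), 5L)
  expect_setequal(agg$ratio[agg$method == "resunet"], ratios)
  # rows come back ordered by method then descending ratio
  rr <- agg[agg$method == "resunet", ]
  expect_equal(rr$ratio, sort(ratios, decreasing = TRUE))
})
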
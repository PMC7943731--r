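test_that("phantom generation is seeded, bounded, and validates inputs", {
  p <- generatePhantom(64, 3, seed = 7)
  expect_s4_class(p, "Phantom")
  expect_equal(sideLength(p), 64)
  expectPhantomRange(p)
  expect_identical(pixels(generatePhantom(64, 3, seed = 7)), pixels(p))
  expect_false(identical(pixels(generatePhantom(64, 3, seed = 8)),
                         pixels(p)))
  expect_error(generatePhantom(15, 0, seed = 1), "invalid geometry")
  expect_error(generatePhantom(64, -1, seed = 1), "invalid argument")
})

test_that("phantom bright structures count as body + blobs + vessel", {
  # complexity 0: only the elliptical body outline is above 0
  p0 <- generatePhantom(64, 0, seed = 7)
  expect_equal(floodFillComponents(pixels(p0), 0), 1L)
  # complexity c >= 1 adds c organ blobs and one vessel
  for (cx in 1:3) {
    for (sd in c(7, 21)) {
      p <- generatePhantom(64, cx, seed = sd)
      expect_equal(floodFillComponents(pixels(p), 0), 1L + cx + 1L,
                   info = sprintf("complexity %d seed %d", cx, sd))
    }
  }
})

test_that("normalisation is an exact affine map onto [-1, 1]", {
  m <- matrix(c(0, 255, 0, 255), 2, 2)
  expect_equal(pixels(normalizeImage(m)), matrix(c(-1, 1, -1, 1), 2, 2))
  r <- randomImage(8, seed = 3)
  nm <- pixels(normalizeImage(r))
  expect_equal(min(nm), -1)
  expect_equal(max(nm), 1)
  expect_equal(cor(as.vector(nm), as.vector(r)), 1)
  # idempotence
  expect_equal(pixels(normalizeImage(nm)), nm, tolerance = 1e-12)
  # constant image degenerates to zeros with a warning
  expect_warning(z <- normalizeImage(matrix(5, 4, 4)), "degenerate")
  expect_equal(pixels(z), matrix(0, 4, 4))
})

test_that("augmentation respects count, involution, and permutation oracle", {
  p <- generatePhantom(32, 2, seed = 9)
  # identity recipe returns the image unchanged
  id <- augmentPhantom(p, augmentationSpec(rotations = 0))
  expect_length(id, 1)
  expect_equal(pixels(id[[1]]), pixels(p))
  # flips are involutions, exactly
  fl <- augmentPhantom(p, augmentationSpec(rotations = 0,
                                           flips = "horizontal"))[[2]]
  fl2 <- augmentPhantom(fl, augmentationSpec(rotations = 0,
                                             flips = "horizontal"))[[2]]
  expect_identical(pixels(fl2), pixels(p))
  vv <- augmentPhantom(p, augmentationSpec(rotations = 0,
                                           flips = "vertical"))[[2]]
  vv2 <- augmentPhantom(vv, augmentationSpec(rotations = 0,
                                             flips = "vertical"))[[2]]
  expect_identical(pixels(vv2), pixels(p))
  # 4 rotations x (1 + horizontal flip) = 8 pairwise-distinct outputs
  out <- augmentPhantom(p, augmentationSpec(
    rotations = c(0, 90, 180, 270), flips = "horizontal"))
  expect_length(out, 8)
  mats <- lapply(out, pixels)
  for (i in 1:7) for (j in (i + 1):8)
    expect_false(identical(mats[[i]], mats[[j]]))
  # 90-degree rotations are exact index permutations
  for (q in 1:3) {
    got <- pixels(augmentPhantom(p, augmentationSpec(
      rotations = 90 * q))[[1]])
    expect_identical(got, rot90Oracle(pixels(p), q))
  }
  # every output honours the range invariant, including interpolated ones
  mixed <- augmentPhantom(p, augmentationSpec(
    rotations = c(0, 37), flips = "vertical", cropFraction = 0.75))
  expect_length(mixed, 4)
  for (im in mixed) expectPhantomRange(im)
  expect_error(augmentationSpec(cropFraction = 0), "invalid argument")
  expect_error(augmentationSpec(cropFraction = 1.2), "invalid argument")
})

test_that("dataset splitting matches the 80/20 protocol", {
  phs <- lapply(1:10, function(i) generatePhantom(16, 0, seed = i))
  sp <- splitDataset(phs, 0.8, seed = 4)
  expect_length(sp@train, 8)
  expect_length(sp@test, 2)
  # same seed, same partition
  sp2 <- splitDataset(phs, 0.8, seed = 4)
  expect_identical(lapply(sp@train, pixels), lapply(sp2@train, pixels))
  # disjointness by identity: no training image equals a test image
  for (tr in sp@train) for (te in sp@test)
    expect_false(identical(pixels(tr), pixels(te)))
  expect_error(splitDataset(list(), 0.8, seed = 1), "invalid argument")
  expect_error(splitDataset(phs, 1.2, seed = 1), "invalid argument")
})

test_that("an augmented corpus of 1130 images splits into 904/226", {
  # counts only: build a light stand-in list, the split logic is the same
  phs <- rep(list(generatePhantom(16, 0, seed = 1)), 1130)
  sp <- splitDataset(phs, 0.8, seed = 2)
  expect_length(sp@train, 904)
  expect_length(sp@test, 226)
})

test_that("generate -> augment -> split is deterministic end to end", {
  runOnce <- function() {
    phs <- lapply(1:4, function(i) generatePhantom(32, 1, seed = 50 + i))
    aug <- unlist(lapply(phs, function(p)
      augmentPhantom(p, augmentationSpec(rotations = c(0, 90),
                                         flips = "horizontal"))),
      recursive = FALSE)
    sp <- splitDataset(aug, 0.8, seed = 3)
    lapply(c(sp@train, sp@test), pixels)
  }
  expect_identical(runOnce(), runOnce())
})

test_that("phantom image and dataset round-trips preserve data", {
  p <- generatePhantom(32, 2, seed = 5)
  tdir <- withr::local_tempdir()
  tifPath <- file.path(tdir, "p.tif")
  writePhantom(p, tifPath)
  expect_equal(pixels(readPhantom(tifPath)), pixels(p), tolerance = 1e-6)
  pngPath <- file.path(tdir, "p.png")
  writePhantom(p, pngPath)
  expect_equal(pixels(readPhantom(pngPath)), pixels(p), tolerance = 4e-3)
  sp <- splitDataset(lapply(1:5, function(i)
    generatePhantom(32, 1, seed = i)), 0.8, seed = 1)
  dsDir <- file.path(tdir, "ds")
  saveDataset(sp, dsDir)
  sp2 <- loadDataset(dsDir)
  expect_length(sp2@train, length(sp@train))
  expect_equal(pixels(sp2@train[[1]]), pixels(sp@train[[1]]),
               tolerance = 1e-6)
  expect_equal(sp2@train[[1]]@label, sp@train[[1]]@label)
})
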
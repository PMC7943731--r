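#' Generate a synthetic mouse-cross-section phantom
#'
#' Builds a square test image emulating a tomographic cross-section of a
#' small animal: a dominant elliptical body outline (a bright rim), smooth
#' low-intensity background and interior tissue, \code{complexity} interior
#' elliptical blobs (organs) with distinct intensities, and — whenever
#' \code{complexity >= 1} — one thin curvilinear vessel-like structure.
#' Bright features are mutually separated by at least two pixels, so after
#' normalisation the connected components above intensity 0 are exactly:
#' one body rim, \code{complexity} blobs, and one vessel (none for
#' \code{complexity = 0}).  All values are normalised to \eqn{[-1, 1]}.
#'
#' @param sideLength integer, image side in pixels (at least 16).
#' @param complexity non-negative integer, number of organ blobs.
#' @param seed integer; fixes all randomness.
#' @return a [Phantom-class].
#' @examples
#' p <- generatePhantom(64, complexity = 3, seed = 7)
#' range(pixels(p))
#' @export
generatePhantom <- function(sideLength, complexity, seed) {
  if (sideLength < 16) stop("invalid geometry: sideLength must be >= 16")
  if (complexity < 0) stop("invalid argument: complexity must be >= 0")
  n <- as.integer(sideLength)
  withSeed(seed, {
    ax <- seq(-1, 1, length.out = n)
    U <- matrix(ax, n, n, byrow = TRUE)   # x coordinate (columns)
    V <- matrix(ax, n, n)                 # y coordinate (rows)

    # smooth dim background
    a <- runif(3, -1, 1)
    img <- -0.96 + 0.05 * (a[1] * U + a[2] * V + a[3] * U * V)

    # body ellipse (outline): semi-axes and tilt jittered per seed
    A <- runif(1, 0.72, 0.82); B <- runif(1, 0.58, 0.68)
    phi <- runif(1, -0.3, 0.3)
    Ur <- cos(phi) * U + sin(phi) * V
    Vr <- -sin(phi) * U + cos(phi) * V
    r <- sqrt((Ur / A)^2 + (Vr / B)^2)
    ringW <- max(0.045, 2.5 / n)          # rim half-width, >= ~1.2 px
    rim <- abs(r - 1) < ringW
    inside <- r < 1 - ringW

    # interior tissue: moderate negative level with smooth texture
    b <- runif(3, -1, 1)
    tissue <- -0.32 + 0.08 * (b[1] * sin(2.2 * U + b[2]) * cos(1.7 * V) +
                                b[3] * U * V)
    img[inside] <- clamp(tissue[inside], -0.45, -0.2)
    img[rim] <- 0.78

    occupied <- rim                       # mask of bright features
    gap <- max(2L, round(n / 32))         # separation in pixels
    dil <- function(mask, k) {
      # binary dilation by a k-pixel chebyshev radius
      out <- mask
      for (d in seq_len(k)) {
        sh <- out
        sh[-1, ] <- sh[-1, ] | out[-nrow(out), ]
        sh[-nrow(out), ] <- sh[-nrow(out), ] | out[-1, ]
        sh[, -1] <- sh[, -1] | out[, -ncol(out)]
        sh[, -ncol(out)] <- sh[, -ncol(out)] | out[, -1]
        out <- sh
      }
      out
    }

    if (complexity >= 1) {
      # vessel: smooth random curve inside the body, drawn with ~1-px pen
      for (attempt in 1:25) {
        t0 <- runif(1, 0, 2 * pi)
        rad0 <- runif(1, 0.15, 0.45)
        cx <- rad0 * cos(t0); cy <- rad0 * sin(t0)
        ang <- runif(1, 0, 2 * pi)
        pts <- matrix(NA_real_, 160, 2)
        for (k in 1:160) {
          pts[k, ] <- c(cx, cy)
          ang <- ang + 0.12 * sin(k / 9 + t0) + rnorm(1, 0, 0.06)
          cx <- cx + 0.011 * cos(ang); cy <- cy + 0.011 * sin(ang)
          rr <- sqrt((cos(phi) * cx + sin(phi) * cy)^2 / A^2 +
                       (-sin(phi) * cx + cos(phi) * cy)^2 / B^2)
          if (rr > 0.72) break
        }
        pts <- pts[stats::complete.cases(pts), , drop = FALSE]
        if (nrow(pts) < 40) next
        ci <- round((pts[, 2] + 1) / 2 * (n - 1)) + 1  # row from y
        cj <- round((pts[, 1] + 1) / 2 * (n - 1)) + 1  # col from x
        vm <- matrix(FALSE, n, n)
        ok <- ci >= 2 & ci <= n - 1 & cj >= 2 & cj <= n - 1
        vm[cbind(ci[ok], cj[ok])] <- TRUE
        vm <- dil(vm, max(1L, round(n / 96)))
        if (sum(vm) < 8) next
        if (!any(vm & dil(occupied, gap))) {
          img[vm] <- 0.85
          occupied <- occupied | vm
          break
        }
      }
    }

    levels <- if (complexity > 0)
      seq(0.45, 0.95, length.out = complexity) else numeric(0)
    placed <- 0
    while (placed < complexity) {
      done <- FALSE
      # if the preferred separation cannot be met, retry with the
      # minimal 1-pixel gap (still disconnected under 8-connectivity)
      # and progressively smaller blobs before giving up
      for (relax in 1:3) {
        g <- if (relax == 1) gap else 1L
        shrink <- c(1, 1, 0.6)[relax]
        for (attempt in 1:400) {
          t0 <- runif(1, 0, 2 * pi); rad0 <- sqrt(runif(1)) * 0.55
          cx <- rad0 * cos(t0); cy <- rad0 * sin(t0)
          ea <- runif(1, 0.07, 0.17) * shrink
          eb <- runif(1, 0.06, 0.14) * shrink
          bphi <- runif(1, 0, pi)
          du <- U - cx; dv <- V - cy
          dur <- cos(bphi) * du + sin(bphi) * dv
          dvr <- -sin(bphi) * du + cos(bphi) * dv
          bm <- (dur / ea)^2 + (dvr / eb)^2 < 1
          if (!any(bm)) next
          if (any(bm & !inside)) next
          if (any(bm & dil(occupied, g))) next
          img[bm] <- levels[placed + 1] + runif(1, -0.02, 0.02)
          occupied <- occupied | bm
          placed <- placed + 1
          done <- TRUE
          break
        }
        if (done) break
      }
      if (!done) stop("could not place all organ blobs; try another seed")
    }

    ph <- normalizeImage(img)
    ph@label <- sprintf("synthetic(side=%d, complexity=%d, seed=%d)",
                        n, as.integer(complexity), as.integer(seed))
    ph
  })
}

#' Normalise an image to the closed interval [-1, 1]
#'
#' Affine map sending the minimum to \eqn{-1} and the maximum to \eqn{+1}.
#' A constant input has no defined range; it is mapped to all zeros with a
#' warning rather than failing, so batch pipelines keep running.
#'
#' @param image numeric matrix or [Phantom-class].
#' @return a [Phantom-class] with values in \eqn{[-1, 1]}.
#' @export
normalizeImage <- function(image) {
  m <- if (is(image, "Phantom")) image@pixels else image
  if (!is.matrix(m) || !is.numeric(m)) stop("image must be a numeric matrix")
  lo <- min(m); hi <- max(m)
  if (hi == lo) {
    warning("degenerate range: constant image mapped to zeros")
    out <- matrix(0, nrow(m), ncol(m))
  } else {
    out <- (m - lo) / (hi - lo) * 2 - 1
  }
  new("Phantom", pixels = out,
      label = if (is(image, "Phantom")) image@label else "")
}

#' Construct an augmentation recipe
#'
#' @param rotations numeric vector of angles in degrees.
#' @param flips character subset of \code{c("horizontal", "vertical")}.
#' @param cropFraction numeric in (0, 1]; see [AugmentationSpec-class].
#' @param seed integer.
#' @return an [AugmentationSpec-class].
#' @export
augmentationSpec <- function(rotations = 0, flips = character(0),
                             cropFraction = 1, seed = 1L) {
  if (length(cropFraction) != 1 || !is.finite(cropFraction) ||
      cropFraction <= 0 || cropFraction > 1)
    stop("invalid argument: cropFraction must lie in (0, 1]")
  new("AugmentationSpec", rotations = as.numeric(rotations),
      flips = as.character(flips), cropFraction = cropFraction,
      seed = as.integer(seed))
}

#' Apply an augmentation recipe to a phantom
#'
#' Produces one output per (rotation, flip) combination, where "no flip" is
#' always included: \code{length(rotations) * (1 + length(flips))} images.
#' Rotations by multiples of 90 degrees are exact index permutations;
#' other angles use bilinear interpolation with constant (zero) padding.
#' When \code{cropFraction < 1}, each output is centre-cropped to that
#' fraction of the side and bilinearly resized back to the original side.
#' All outputs stay within \eqn{[-1, 1]} (interpolation is a convex
#' combination of in-range values and the zero pad).
#'
#' @param image a [Phantom-class] (normalised).
#' @param spec an [AugmentationSpec-class].
#' @return list of [Phantom-class] objects.
#' @export
augmentPhantom <- function(image, spec) {
  stopifnot(is(image, "Phantom"), is(spec, "AugmentationSpec"))
  validObject(spec)
  m <- image@pixels
  n <- nrow(m)
  out <- list()
  for (ang in spec@rotations) {
    rot <- rotateImage(m, ang, pad = 0)
    variants <- c(list(rot), lapply(spec@flips, function(f)
      flipImage(rot, f)))
    tags <- c("", paste0("+", spec@flips))
    for (i in seq_along(variants)) {
      img <- variants[[i]]
      if (spec@cropFraction < 1) {
        side <- max(2L, round(n * spec@cropFraction))
        off <- floor((n - side) / 2)
        img <- bilinearResize(img[(off + 1):(off + side),
                                  (off + 1):(off + side), drop = FALSE], n)
      }
      out[[length(out) + 1]] <- new("Phantom", pixels = clamp(img),
        label = sprintf("%s|rot=%g%s%s", image@label, ang, tags[i],
                        if (spec@cropFraction < 1)
                          sprintf("|crop=%g", spec@cropFraction) else ""))
    }
  }
  out
}

#' Split phantoms into train and test sets
#'
#' Random disjoint partition with \code{round(n * trainFraction)} training
#' images, reproducible under \code{seed}.
#'
#' @param phantoms non-empty list of [Phantom-class] objects.
#' @param trainFraction numeric in (0, 1).
#' @param seed integer.
#' @return a [DatasetSplit-class].
#' @export
splitDataset <- function(phantoms, trainFraction = 0.8, seed = 1L) {
  if (length(phantoms) == 0) stop("invalid argument: empty phantom list")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("invalid argument: trainFraction must lie strictly in (0, 1)")
  n <- length(phantoms)
  nTrain <- round(n * trainFraction)
  nTrain <- min(max(nTrain, 1L), n - 1L)
  idx <- withSeed(seed, sample.int(n, nTrain))
  new("DatasetSplit", train = phantoms[idx], test = phantoms[-idx],
      trainFraction = trainFraction)
}

#' Read and write phantom images
#'
#' \code{writePhantom} stores a phantom as grayscale PNG (values mapped
#' from \eqn{[-1,1]} to \eqn{[0,1]}, 8-bit) or as 32-bit float TIFF
#' (lossless, values stored as-is); \code{readPhantom} inverts the mapping.
#' The format follows the file extension (\code{.png}, \code{.tif},
#' \code{.tiff}).
#'
#' @param phantom a [Phantom-class].
#' @param path file path.
#' @return \code{readPhantom} returns a [Phantom-class];
#'   \code{writePhantom} returns \code{path} invisibly.
#' @export
writePhantom <- function(phantom, path) {
  stopifnot(is(phantom, "Phantom"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(clamp((phantom@pixels + 1) / 2, 0, 1), path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF((clamp(phantom@pixels) + 1) / 2, path,
                    bits.per.sample = 32L, reduce = FALSE)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' @rdname writePhantom
#' @export
readPhantom <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m <- m * 2 - 1
  } else if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m <- m * 2 - 1
  } else stop("unsupported image format: ", ext)
  new("Phantom", pixels = m, label = basename(path))
}

#' Persist or load a phantom dataset directory
#'
#' The dataset is stored as one float TIFF per image plus a
#' \code{manifest.json} recording ids, labels, the split membership and
#' provenance, so a saved dataset can be reloaded bit-identically.
#'
#' @param split a [DatasetSplit-class].
#' @param dir directory (created if missing).
#' @return \code{saveDataset} returns \code{dir} invisibly;
#'   \code{loadDataset} returns a [DatasetSplit-class].
#' @export
saveDataset <- function(split, dir) {
  stopifnot(is(split, "DatasetSplit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  writeSet <- function(set, role) {
    for (i in seq_along(set)) {
      id <- sprintf("%s_%04d", role, i)
      writePhantom(set[[i]], file.path(dir, paste0(id, ".tif")))
      rows[[length(rows) + 1]] <<- list(id = id, role = role,
                                        label = set[[i]]@label)
    }
  }
  writeSet(split@train, "train")
  writeSet(split@test, "test")
  manifest <- list(trainFraction = split@trainFraction, images = rows)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname saveDataset
#' @param dir dataset directory containing \code{manifest.json}.
#' @export
loadDataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  train <- list(); test <- list()
  for (row in manifest$images) {
    ph <- readPhantom(file.path(dir, paste0(row$id, ".tif")))
    ph@label <- row$label
    if (row$role == "train") train[[length(train) + 1]] <- ph
    else test[[length(test) + 1]] <- ph
  }
  new("DatasetSplit", train = train, test = test,
      trainFraction = manifest$trainFraction)
}

#' Piecewise-constant nested-ellipse phantom
#'
#' A deterministic piecewise-constant test image: two nested ellipses on a
#' flat background (levels -1, 0.2, 0.8).  Exactly the kind of image the
#' total-variation prior favours, used as the reconstruction fixture for
#' the TV baseline.
#'
#' @param sideLength integer, image side (at least 16).
#' @return a [Phantom-class].
#' @export
nestedEllipsePhantom <- function(sideLength = 64) {
  if (sideLength < 16) stop("invalid geometry: sideLength must be >= 16")
  n <- as.integer(sideLength)
  ax <- seq(-1, 1, length.out = n)
  U <- matrix(ax, n, n, byrow = TRUE)
  V <- matrix(ax, n, n)
  img <- matrix(-1, n, n)
  img[(U / 0.78)^2 + (V / 0.62)^2 < 1] <- 0.2
  img[((U - 0.1) / 0.38)^2 + ((V + 0.05) / 0.3)^2 < 1] <- 0.8
  new("Phantom", pixels = img, label = sprintf("nested-ellipses(%d)", n))
}
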
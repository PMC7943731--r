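# Internal helpers shared across modules.

# Row-major vectorisation: image row i, column j -> index (i-1)*N + j.
# R matrices are column-major, so this is the flatten of the transpose.
vecRowMajor <- function(x) as.vector(t(x))

# Inverse of vecRowMajor.
unvecRowMajor <- function(v, n) matrix(v, n, n, byrow = TRUE)

clamp <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

# Bilinear sampling of matrix `img` at fractional (row, col) positions.
# Out-of-range samples return `pad`.
bilinearSample <- function(img, rows, cols, pad = 0) {
  n <- nrow(img); m <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  get <- function(r, c) {
    ok <- r >= 1 & r <= n & c >= 1 & c <= m
    out <- rep(pad, length(r))
    out[ok] <- img[cbind(r[ok], c[ok])]
    out
  }
  v00 <- get(r0, c0);     v01 <- get(r0, c0 + 1)
  v10 <- get(r0 + 1, c0); v11 <- get(r0 + 1, c0 + 1)
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

# Resize a square matrix to side `n` with bilinear interpolation
# (pixel-centre alignment).
bilinearResize <- function(img, n) {
  s <- nrow(img)
  if (s == n) return(img)
  # output pixel centre (i-0.5)/n maps to input matrix index
  # (i-0.5)*(s/n) + 0.5 under pixel-centre alignment
  pos <- (seq_len(n) - 0.5) * (s / n) + 0.5
  grid <- expand.grid(r = pos, c = pos)
  # clamp sampling positions to the valid range (replicate border)
  rr <- clamp(grid$r, 1, s); cc <- clamp(grid$c, 1, s)
  matrix(bilinearSample(img, rr, cc), n, n)
}

# Exact rotations by multiples of 90 degrees (counter-clockwise) via index
# permutation; other angles use bilinear interpolation about the image
# centre with constant padding.
rotateImage <- function(img, degrees, pad = 0) {
  d <- degrees %% 360
  if (isTRUE(all.equal(d, 0))) return(img)
  if (isTRUE(all.equal(d %% 90, 0))) {
    k <- round(d / 90) %% 4
    out <- img
    for (i in seq_len(k)) out <- t(out)[ncol(out):1, , drop = FALSE]
    return(out)
  }
  n <- nrow(img)
  ctr <- (n + 1) / 2
  th <- d * pi / 180
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  # inverse rotation of output coordinates into the source image; rows grow
  # downward, so a counter-clockwise image rotation uses the transpose of
  # the usual plane rotation
  dy <- g$r - ctr; dx <- g$c - ctr
  sr <- ctr + cos(th) * dy - sin(th) * dx
  sc <- ctr + sin(th) * dy + cos(th) * dx
  matrix(bilinearSample(img, sr, sc, pad = pad), n, n)
}

flipImage <- function(img, direction) {
  switch(direction,
    horizontal = img[, ncol(img):1, drop = FALSE],
    vertical = img[nrow(img):1, , drop = FALSE],
    stop("unknown flip direction: ", direction)
  )
}

# md5 of an in-memory object via its canonical JSON serialisation
md5OfObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
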
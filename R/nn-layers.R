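# Layer primitives for the reconstruction networks.  Activations are
# H x W x C arrays; convolution kernels live in (k*k*Cin) x Cout matrices
# (column-major flattening of a (k, k, Cin) array), which is what the
# compiled kernels expect.  Forward functions return list(out, cache);
# backward functions return the input gradient plus parameter gradients
# named like the parameters.

initConv <- function(k, cin, cout) {
  list(W = matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                  k * k * cin, cout),
       b = numeric(cout), k = as.integer(k))
}

initUpconv <- function(cin, cout) {
  list(W = matrix(rnorm(4 * cin * cout, sd = sqrt(2 / (4 * cin))),
                  4 * cin, cout),
       b = numeric(cout))
}

initBN <- function(ch) list(gamma = rep(1, ch), beta = numeric(ch))

asCube <- function(x) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  x
}

# batch normalisation over the spatial dimensions of a single sample
# (batch size 1 throughout, so batch statistics are per-channel spatial
# statistics); training-mode statistics are also used at inference, which
# keeps the forward pass deterministic and input-contained
bnFw <- function(p, x, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  mu <- colMeans(xm)
  v <- colMeans(xm * xm) - mu * mu
  istd <- 1 / sqrt(pmax(v, 0) + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, istd, "*")
  out <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, istd = istd, d = d))
}

bnBw <- function(p, cache, go) {
  d <- cache$d
  n <- d[1] * d[2]
  gom <- matrix(go, n, d[3])
  dgamma <- colSums(gom * cache$xhat)
  dbeta <- colSums(gom)
  dxhat <- sweep(gom, 2, p$gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  gx <- sweep(
    dxhat - sweep(matrix(1, n, 1) %*% t(s1), 2, rep(n, d[3]), "/") -
      sweep(cache$xhat, 2, s2 / n, "*"),
    2, cache$istd, "*")
  dim(gx) <- d
  list(gx = gx, gamma = dgamma, beta = dbeta)
}

# one conv (+ optional BN) + ReLU unit
unitFw <- function(params, name, x, useBN) {
  cp <- params[[paste0(name, ".conv")]]
  z <- .conv2dFw(x, cp$W, cp$b, cp$k)
  cache <- list(x = x)
  if (useBN) {
    r <- bnFw(params[[paste0(name, ".bn")]], z)
    cache$bn <- r$cache
    z <- r$out
  }
  cache$mask <- z > 0
  list(out = z * cache$mask, cache = cache)
}

unitBw <- function(params, name, cache, go, grads, useBN,
                   relu = TRUE) {
  if (relu) go <- go * cache$mask
  if (useBN) {
    r <- bnBw(params[[paste0(name, ".bn")]], cache$bn, go)
    grads[[paste0(name, ".bn")]] <- list(gamma = r$gamma, beta = r$beta)
    go <- r$gx
  }
  cp <- params[[paste0(name, ".conv")]]
  r <- .conv2dBw(cache$x, cp$W, go, cp$k)
  grads[[paste0(name, ".conv")]] <- list(W = r$gW, b = as.vector(r$gb))
  list(gx = r$gx, grads = grads)
}

# plain double-conv block: conv(+BN)+ReLU twice
doubleFw <- function(params, prefix, x, useBN) {
  u1 <- unitFw(params, paste0(prefix, ".u1"), x, useBN)
  u2 <- unitFw(params, paste0(prefix, ".u2"), u1$out, useBN)
  list(out = u2$out, cache = list(u1 = u1$cache, u2 = u2$cache))
}

doubleBw <- function(params, prefix, cache, go, grads, useBN) {
  r2 <- unitBw(params, paste0(prefix, ".u2"), cache$u2, go, grads, useBN)
  r1 <- unitBw(params, paste0(prefix, ".u1"), cache$u1, r2$gx, r2$grads,
               useBN)
  list(gx = r1$gx, grads = r1$grads)
}

# residual block: [conv-BN-ReLU, conv-BN] + shortcut (1x1 conv when the
# channel counts differ), then ReLU on the sum
resFw <- function(params, prefix, x, useBN) {
  u1 <- unitFw(params, paste0(prefix, ".u1"), x, useBN)
  c2 <- params[[paste0(prefix, ".u2.conv")]]
  z2 <- .conv2dFw(u1$out, c2$W, c2$b, c2$k)
  cache <- list(u1 = u1$cache, x2 = u1$out)
  if (useBN) {
    r <- bnFw(params[[paste0(prefix, ".u2.bn")]], z2)
    cache$bn2 <- r$cache
    z2 <- r$out
  }
  scName <- paste0(prefix, ".sc.conv")
  if (!is.null(params[[scName]])) {
    sp <- params[[scName]]
    short <- .conv2dFw(x, sp$W, sp$b, sp$k)
    cache$hasSc <- TRUE
  } else {
    short <- x
    cache$hasSc <- FALSE
  }
  s <- z2 + short
  cache$x <- x
  cache$mask <- s > 0
  list(out = s * cache$mask, cache = cache)
}

resBw <- function(params, prefix, cache, go, grads, useBN) {
  ds <- go * cache$mask
  # shortcut branch
  if (cache$hasSc) {
    sp <- params[[paste0(prefix, ".sc.conv")]]
    r <- .conv2dBw(cache$x, sp$W, ds, sp$k)
    grads[[paste0(prefix, ".sc.conv")]] <- list(W = r$gW,
                                                b = as.vector(r$gb))
    dxShort <- r$gx
  } else {
    dxShort <- ds
  }
  # main branch
  dz2 <- ds
  if (useBN) {
    r <- bnBw(params[[paste0(prefix, ".u2.bn")]], cache$bn2, dz2)
    grads[[paste0(prefix, ".u2.bn")]] <- list(gamma = r$gamma,
                                              beta = r$beta)
    dz2 <- r$gx
  }
  c2 <- params[[paste0(prefix, ".u2.conv")]]
  r <- .conv2dBw(cache$x2, c2$W, dz2, c2$k)
  grads[[paste0(prefix, ".u2.conv")]] <- list(W = r$gW, b = as.vector(r$gb))
  r1 <- unitBw(params, paste0(prefix, ".u1"), cache$u1, r$gx, grads, useBN)
  list(gx = r1$gx + dxShort, grads = r1$grads)
}

blockFw <- function(params, prefix, x, arch) {
  if (arch$residual) resFw(params, prefix, x, arch$useBatchnorm)
  else doubleFw(params, prefix, x, arch$useBatchnorm)
}

blockBw <- function(params, prefix, cache, go, grads, arch) {
  if (arch$residual) resBw(params, prefix, cache, go, grads,
                           arch$useBatchnorm)
  else doubleBw(params, prefix, cache, go, grads, arch$useBatchnorm)
}

concatChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}
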
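#' Describe a reconstruction network architecture
#'
#' Three families are available, all mapping an \eqn{N \times N} proxy
#' image to an \eqn{N \times N} reconstruction with 3x3 convolutions
#' (stride 1), 2x2 max pooling and 2x2-stride-2 transposed convolutions:
#' \describe{
#'   \item{\code{cnn3}}{three convolutional layers (9x9, 5x5, 5x5 kernels;
#'     64, 32, 1 channels; ReLU between, linear output).}
#'   \item{\code{unet}}{encoder-decoder with skip concatenations;
#'     \code{depth} pooling levels and \code{baseChannels} channels at the
#'     top level, doubling per level.}
#'   \item{\code{resunet}}{same topology with residual blocks (two 3x3
#'     convolutions with batch normalisation and ReLU plus an identity
#'     shortcut; a 1x1 convolution matches channels where they differ).}
#' }
#' U-Net families require the image side to be divisible by
#' \code{2^depth}.  The defaults (depth 3, base 8) are the desk-scale
#' profile; \code{depth = 4, baseChannels = 64} is the conventional
#' full-size shape.
#'
#' @param family \code{"cnn3"}, \code{"unet"} or \code{"resunet"}.
#' @param depth integer, encoder levels (unet/resunet).
#' @param baseChannels integer, channels at the first level.
#' @param useBatchnorm logical; default \code{TRUE} for resunet only.
#' @param cnnChannels integer vector of 3 channel counts for cnn3.
#' @return a list describing the architecture.
#' @export
networkSpec <- function(family = c("unet", "resunet", "cnn3"), depth = 3L,
                        baseChannels = 8L, useBatchnorm = NULL,
                        cnnChannels = c(64L, 32L, 1L)) {
  family <- match.arg(family)
  if (is.null(useBatchnorm)) useBatchnorm <- family == "resunet"
  stopifnot(depth >= 1, baseChannels >= 1, length(cnnChannels) == 3,
            cnnChannels[3] == 1)
  list(family = family, depth = as.integer(depth),
       baseChannels = as.integer(baseChannels),
       useBatchnorm = isTRUE(useBatchnorm),
       residual = family == "resunet",
       cnnChannels = as.integer(cnnChannels),
       convKernel = 3L, poolKernel = 2L, upKernel = 2L, upStride = 2L)
}

# parameter construction; RNG draws happen in a fixed name order so the
# initialisation is reproducible under a seed
initBlockParams <- function(params, prefix, cin, cout, arch) {
  k <- arch$convKernel
  params[[paste0(prefix, ".u1.conv")]] <- initConv(k, cin, cout)
  if (arch$useBatchnorm)
    params[[paste0(prefix, ".u1.bn")]] <- initBN(cout)
  params[[paste0(prefix, ".u2.conv")]] <- initConv(k, cout, cout)
  if (arch$useBatchnorm)
    params[[paste0(prefix, ".u2.bn")]] <- initBN(cout)
  if (arch$residual && cin != cout)
    params[[paste0(prefix, ".sc.conv")]] <- initConv(1, cin, cout)
  params
}

initNetworkParams <- function(arch) {
  params <- list()
  if (arch$family == "cnn3") {
    ch <- arch$cnnChannels
    params[["c1.conv"]] <- initConv(9, 1, ch[1])
    params[["c2.conv"]] <- initConv(5, ch[1], ch[2])
    params[["c3.conv"]] <- initConv(5, ch[2], ch[3])
    return(params)
  }
  d <- arch$depth
  b <- arch$baseChannels
  chans <- b * 2^(seq_len(d) - 1)
  cin <- 1
  for (l in seq_len(d)) {
    params <- initBlockParams(params, paste0("enc", l), cin, chans[l], arch)
    cin <- chans[l]
  }
  params <- initBlockParams(params, "bottom", chans[d], 2 * chans[d], arch)
  for (l in rev(seq_len(d))) {
    params[[paste0("up", l)]] <- initUpconv(2 * chans[l], chans[l])
    params <- initBlockParams(params, paste0("dec", l), 2 * chans[l],
                              chans[l], arch)
  }
  params[["final.conv"]] <- initConv(1, chans[1], 1)
  params
}

#' Build a learned reconstruction model
#'
#' Couples a fixed transpose-proxy stage (the measurement operator's
#' \eqn{K^T}) with a freshly initialised network of the given family.
#' Weight initialisation is He-normal and fully determined by \code{seed}.
#'
#' @param spec architecture from [networkSpec()].
#' @param matrix a [MeasurementMatrix-class].
#' @param seed integer.
#' @return an untrained [ReconModel-class].
#' @export
buildModel <- function(spec, matrix, seed = 1L) {
  stopifnot(is(matrix, "MeasurementMatrix"))
  n <- matrix@gridSide
  if (spec$family != "cnn3") {
    div <- 2^spec$depth
    if (n %% div != 0)
      stop(sprintf(
        "architecture error: side %d is not divisible by 2^%d = %d (level %d)",
        n, spec$depth, div, spec$depth))
  }
  params <- withSeed(seed, initNetworkParams(spec))
  new("ReconModel", family = spec$family, arch = spec, params = params,
      matrix = matrix,
      trainHistory = data.frame(epoch = integer(0), loss = numeric(0)),
      config = list(), seed = as.integer(seed))
}

# full network forward pass; input and output are H x W x 1 arrays
netForward <- function(params, x, arch) {
  if (arch$family == "cnn3") {
    caches <- list(x1 = x)
    c1 <- params[["c1.conv"]]
    z1 <- .conv2dFw(x, c1$W, c1$b, c1$k)
    caches$m1 <- z1 > 0
    h1 <- z1 * caches$m1
    caches$x2 <- h1
    c2 <- params[["c2.conv"]]
    z2 <- .conv2dFw(h1, c2$W, c2$b, c2$k)
    caches$m2 <- z2 > 0
    h2 <- z2 * caches$m2
    caches$x3 <- h2
    c3 <- params[["c3.conv"]]
    out <- .conv2dFw(h2, c3$W, c3$b, c3$k)
    return(list(out = out, cache = caches))
  }
  d <- arch$depth
  cache <- list(skips = vector("list", d), enc = vector("list", d),
                pool = vector("list", d), up = vector("list", d),
                dec = vector("list", d), cat = vector("list", d))
  h <- x
  for (l in seq_len(d)) {
    r <- blockFw(params, paste0("enc", l), h, arch)
    cache$enc[[l]] <- r$cache
    cache$skips[[l]] <- r$out
    p <- .maxpool2Fw(r$out)
    cache$pool[[l]] <- list(idx = p$idx, dims = dim(r$out))
    h <- p$out
  }
  r <- blockFw(params, "bottom", h, arch)
  cache$bottom <- r$cache
  h <- r$out
  for (l in rev(seq_len(d))) {
    up <- params[[paste0("up", l)]]
    cache$up[[l]] <- h
    u <- .upconv2Fw(h, up$W, up$b)
    cat <- concatChannels(cache$skips[[l]], u)
    cache$cat[[l]] <- dim(cache$skips[[l]])[3]
    r <- blockFw(params, paste0("dec", l), cat, arch)
    cache$dec[[l]] <- r$cache
    h <- r$out
  }
  fc <- params[["final.conv"]]
  out <- .conv2dFw(h, fc$W, fc$b, fc$k)
  cache$final <- h
  list(out = out, cache = cache)
}

netBackward <- function(params, cache, go, arch) {
  grads <- list()
  if (arch$family == "cnn3") {
    c3 <- params[["c3.conv"]]
    r3 <- .conv2dBw(cache$x3, c3$W, go, c3$k)
    grads[["c3.conv"]] <- list(W = r3$gW, b = as.vector(r3$gb))
    g <- r3$gx * cache$m2
    c2 <- params[["c2.conv"]]
    r2 <- .conv2dBw(cache$x2, c2$W, g, c2$k)
    grads[["c2.conv"]] <- list(W = r2$gW, b = as.vector(r2$gb))
    g <- r2$gx * cache$m1
    c1 <- params[["c1.conv"]]
    r1 <- .conv2dBw(cache$x1, c1$W, g, c1$k)
    grads[["c1.conv"]] <- list(W = r1$gW, b = as.vector(r1$gb))
    return(grads)
  }
  d <- arch$depth
  fc <- params[["final.conv"]]
  rf <- .conv2dBw(cache$final, fc$W, go, fc$k)
  grads[["final.conv"]] <- list(W = rf$gW, b = as.vector(rf$gb))
  g <- rf$gx
  dskip <- vector("list", d)
  for (l in seq_len(d)) {
    r <- blockBw(params, paste0("dec", l), cache$dec[[l]], g, grads, arch)
    grads <- r$grads
    nSkip <- cache$cat[[l]]
    gcat <- r$gx
    dskip[[l]] <- gcat[, , seq_len(nSkip), drop = FALSE]
    gu <- gcat[, , nSkip + seq_len(dim(gcat)[3] - nSkip), drop = FALSE]
    up <- params[[paste0("up", l)]]
    ru <- .upconv2Bw(cache$up[[l]], up$W, gu)
    grads[[paste0("up", l)]] <- list(W = ru$gW, b = as.vector(ru$gb))
    g <- ru$gx
  }
  r <- blockBw(params, "bottom", cache$bottom, g, grads, arch)
  grads <- r$grads
  g <- r$gx
  for (l in rev(seq_len(d))) {
    pc <- cache$pool[[l]]
    g <- .maxpool2Bw(pc$idx, g, pc$dims[1], pc$dims[2], pc$dims[3])
    g <- g + dskip[[l]]
    r <- blockBw(params, paste0("enc", l), cache$enc[[l]], g, grads, arch)
    grads <- r$grads
    g <- r$gx
  }
  grads
}
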
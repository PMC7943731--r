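#' Training configuration
#'
#' The experimental recipe: L1 (mean-absolute-error) loss minimised by the
#' Adam optimiser with learning rate 0.005 and batch size 1.  Plain SGD is
#' selectable.  All randomness (weight order shuffling) is driven by
#' \code{seed}.
#'
#' @param learningRate positive real; default 0.005.
#' @param batchSize integer \eqn{\ge 1}; gradients are averaged over the
#'   batch before the update. Default 1.
#' @param epochs integer \eqn{\ge 1}.
#' @param optimizer \code{"adam"} (default) or \code{"sgd"}.
#' @param loss only \code{"l1"}.
#' @param seed integer.
#' @param noiseSigma numeric \eqn{\ge 0}; measurement-noise level used
#'   when pairing phantoms with measurement vectors.
#' @param shuffle logical; reshuffle sample order each epoch.
#' @param verbose logical; print one line per epoch.
#' @return validated list of settings.
#' @export
trainConfig <- function(learningRate = 0.005, batchSize = 1L, epochs = 20L,
                        optimizer = c("adam", "sgd"), loss = "l1",
                        seed = 1L, noiseSigma = 0, shuffle = TRUE,
                        verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  stopifnot(learningRate > 0, batchSize >= 1, epochs >= 1,
            identical(loss, "l1"), noiseSigma >= 0)
  list(learningRate = learningRate, batchSize = as.integer(batchSize),
       epochs = as.integer(epochs), optimizer = optimizer, loss = loss,
       seed = as.integer(seed), noiseSigma = noiseSigma,
       shuffle = isTRUE(shuffle), verbose = isTRUE(verbose))
}

# map over the (possibly nested) numeric leaves of a parameter list;
# `k` is excluded (kernel size bookkeeping, not a weight)
paramLeaves <- function(params) {
  out <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    for (f in names(p)) {
      if (f == "k") next
      out[[paste0(nm, "$", f)]] <- p[[f]]
    }
  }
  out
}

adamInit <- function(params) {
  leaves <- paramLeaves(params)
  zero <- lapply(leaves, function(x) x * 0)
  list(m = zero, v = zero, t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      key <- paste0(nm, "$", f)
      g <- grads[[nm]][[f]]
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g * g
      mhat <- state$m[[key]] / (1 - beta1^state$t)
      vhat <- state$v[[key]] / (1 - beta2^state$t)
      params[[nm]][[f]] <- params[[nm]][[f]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

sgdStep <- function(params, grads, lr) {
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * grads[[nm]][[f]]
    }
  }
  params
}

addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) for (f in names(b[[nm]]))
    a[[nm]][[f]] <- a[[nm]][[f]] + b[[nm]][[f]]
  a
}

scaleGrads <- function(a, s) {
  for (nm in names(a)) for (f in names(a[[nm]]))
    a[[nm]][[f]] <- a[[nm]][[f]] * s
  a
}

#' Train a reconstruction model
#'
#' Pairs every training phantom with its measurement vector
#' \eqn{v = K x} (plus optional noise) under the model's operator, feeds
#' the transpose proxy \eqn{K^T v} through the network, and minimises the
#' mean absolute error (L1 loss) against the ground-truth image.  Records
#' the epoch-mean training loss.  The whole run is reproducible under
#' \code{cfg$seed}.
#'
#' @param model an untrained or previously trained [ReconModel-class].
#' @param split a [DatasetSplit-class]; only the training set is used.
#' @param cfg configuration from [trainConfig()].
#' @return the updated [ReconModel-class] with \code{trainHistory} filled.
#' @export
trainModel <- function(model, split, cfg = trainConfig()) {
  stopifnot(is(model, "ReconModel"), is(split, "DatasetSplit"))
  train <- split@train
  if (length(train) == 0) stop("invalid argument: empty training split")
  K <- model@matrix
  arch <- model@arch
  params <- model@params
  n <- K@gridSide

  withSeed(cfg$seed, {
    # fixed measurement/proxy pairs (noise drawn once, before training)
    proxies <- vector("list", length(train))
    targets <- vector("list", length(train))
    for (i in seq_along(train)) {
      v <- measure(K, train[[i]], noiseSigma = cfg$noiseSigma)
      proxies[[i]] <- asCube(proxyImage(K, v))
      targets[[i]] <- train[[i]]@pixels
    }
    state <- if (cfg$optimizer == "adam") adamInit(params) else NULL
    history <- data.frame(epoch = integer(0), loss = numeric(0))
    nTr <- length(train)
    for (ep in seq_len(cfg$epochs)) {
      epStart <- proc.time()[["elapsed"]]
      ord <- if (cfg$shuffle) sample.int(nTr) else seq_len(nTr)
      epochLoss <- 0
      acc <- NULL
      inBatch <- 0L
      for (i in ord) {
        fw <- netForward(params, proxies[[i]], arch)
        diff <- fw$out[, , 1] - targets[[i]]
        loss <- mean(abs(diff))
        if (!is.finite(loss))
          stop("training diverged: non-finite loss at epoch ", ep)
        epochLoss <- epochLoss + loss
        go <- asCube(sign(diff) / length(diff))
        g <- netBackward(params, fw$cache, go, arch)
        acc <- addGrads(acc, g)
        inBatch <- inBatch + 1L
        if (inBatch == cfg$batchSize || i == ord[nTr]) {
          if (inBatch > 1L) acc <- scaleGrads(acc, 1 / inBatch)
          if (cfg$optimizer == "adam") {
            st <- adamStep(params, acc, state, cfg$learningRate)
            params <- st$params
            state <- st$state
          } else {
            params <- sgdStep(params, acc, cfg$learningRate)
          }
          acc <- NULL
          inBatch <- 0L
        }
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = epochLoss / nTr))
      if (cfg$verbose)
        message(sprintf("epoch %d  mean L1 loss %.6f  (%.2fs)", ep,
                        epochLoss / nTr,
                        proc.time()[["elapsed"]] - epStart))
    }
    model@params <- params
    model@trainHistory <- rbind(model@trainHistory, history)
    model@config <- cfg
    model
  })
}

#' Reconstruct an image from a measurement vector
#'
#' Applies the fixed transpose-proxy stage and the trained network, then
#' clamps the output to \eqn{[-1, 1]}.
#'
#' @param model a [ReconModel-class].
#' @param v a [MeasurementVector-class] or numeric vector matching the
#'   model's operator.
#' @return a [Phantom-class].
#' @name reconstruct
#' @export
setMethod("reconstruct", "ReconModel", function(model, v) {
  proxy <- proxyImage(model@matrix, v)
  fw <- netForward(model@params, asCube(proxy), model@arch)
  new("Phantom", pixels = clamp(fw$out[, , 1]),
      label = sprintf("recon(%s)", model@family))
})

evaluateOnSplit <- function(model, split, cfg = NULL, methodName = NULL,
                            ssimCfg = ssimConfig()) {
  ratio <- model@matrix@undersamplingRatio
  nm <- if (is.null(methodName)) model@family else methodName
  rows <- lapply(seq_along(split@test), function(i) {
    x <- split@test[[i]]
    v <- measure(model@matrix, x)
    rec <- reconstruct(model, v)
    metricRecord(sprintf("test_%04d", i), nm, ratio,
                 ssim(rec, x, ssimCfg), psnr(rec, x))
  })
  do.call(rbind, rows)
}

proxyBaselineRecords <- function(K, split, ssimCfg = ssimConfig()) {
  rows <- lapply(seq_along(split@test), function(i) {
    x <- split@test[[i]]
    v <- measure(K, x)
    prox <- clamp(proxyImage(K, v))
    metricRecord(sprintf("test_%04d", i), "proxy-input",
                 K@undersamplingRatio, ssim(prox, x@pixels, ssimCfg),
                 psnr(prox, x@pixels))
  })
  do.call(rbind, rows)
}

#' Train and compare network families across undersampling ratios
#'
#' Trains one model per (family, ratio) pair on the training split,
#' evaluates SSIM/PSNR on the test split, and always includes the
#' untrained transpose-proxy baseline (\code{"proxy-input"}) so every
#' learned method's improvement is measured against its own input.
#'
#' @param split a [DatasetSplit-class].
#' @param ratios numeric vector of undersampling ratios in (0, 1].
#' @param families character subset of
#'   \code{c("cnn3", "unet", "resunet")}.
#' @param cfg a [trainConfig()] shared by all families, or a named list
#'   with one configuration per family.
#' @param specs optional named list of [networkSpec()] per family.
#' @param seed integer; drives matrix construction and per-run training
#'   seeds.
#' @return list with elements \code{records} (per-image data.frame) and
#'   \code{report} (the [aggregateMetrics()] summary).
#' @export
compareFamilies <- function(split, ratios = c(0.5, 0.3, 0.1, 0.05),
                            families = c("cnn3", "unet", "resunet"),
                            cfg = trainConfig(), specs = NULL,
                            seed = 1L) {
  if (length(ratios) == 0) stop("invalid argument: ratios must be non-empty")
  stopifnot(all(ratios > 0 & ratios <= 1))
  n <- sideLength(split@train[[1]])
  records <- list()
  for (ri in seq_along(ratios)) {
    K <- gaussianMatrix(n, ratios[ri], seed = seed + 1000L * ri)
    records[[length(records) + 1]] <- proxyBaselineRecords(K, split)
    for (fam in families) {
      spec <- if (!is.null(specs) && !is.null(specs[[fam]])) specs[[fam]]
              else networkSpec(fam)
      model <- buildModel(spec, K, seed = seed + 17L * ri)
      runCfg <- if (!is.null(cfg$epochs)) cfg else cfg[[fam]]
      runCfg$seed <- runCfg$seed + 31L * ri
      model <- trainModel(model, split, runCfg)
      records[[length(records) + 1]] <- evaluateOnSplit(model, split)
    }
  }
  records <- do.call(rbind, records)
  list(records = records, report = aggregateMetrics(records))
}
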
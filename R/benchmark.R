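#' Benchmark configuration
#'
#' Builds and validates the configuration of the end-to-end benchmark:
#' phantom recipe (or an existing dataset directory), the undersampling
#' ratio grid, the methods to run, per-method settings, seed and output
#' directory.  Unknown keys are rejected — a typo silently dropping a
#' setting would corrupt a benchmark.
#'
#' Defaults are the desk-scale profile: 64x64 phantoms, 200 images,
#' depth-3/base-8 networks, 20 epochs, ratio grid
#' \code{c(0.5, 0.3, 0.1, 0.05)}.
#'
#' @param ... configuration keys; see Details.
#' @details Recognised keys and defaults:
#' \itemize{
#'   \item \code{outputDir} (required for [runBenchmark()])
#'   \item \code{datasetDir = NULL}: load instead of generating
#'   \item \code{nPhantoms = 200}, \code{sideLength = 64},
#'     \code{complexity = 3}, \code{trainFraction = 0.8}
#'   \item \code{ratios = c(0.5, 0.3, 0.1, 0.05)} (all in (0, 1])
#'   \item \code{methods = c("proxy-input", "cnn3", "unet", "resunet",
#'     "tvmin")}
#'   \item \code{epochs = 20}, \code{learningRate = 0.005},
#'     \code{batchSize = 1}, \code{optimizer = "adam"}
#'   \item \code{depth = 3}, \code{baseChannels = 8}
#'   \item \code{tvLambda = 0.002}, \code{tvIters = 150}
#'   \item \code{seed = 1}
#'   \item \code{writeImages = FALSE}: also write reconstruction PNGs
#' }
#' @return validated configuration list.
#' @export
benchmarkConfig <- function(...) {
  defaults <- list(
    outputDir = NULL, datasetDir = NULL,
    nPhantoms = 200L, sideLength = 64L, complexity = 3L,
    trainFraction = 0.8,
    ratios = c(0.5, 0.3, 0.1, 0.05),
    methods = c("proxy-input", "cnn3", "unet", "resunet", "tvmin"),
    epochs = 20L, learningRate = 0.005, batchSize = 1L,
    optimizer = "adam",
    depth = 3L, baseChannels = 8L,
    tvLambda = 0.002, tvIters = 150L,
    seed = 1L, writeImages = FALSE)
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("config error: unknown keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, user)
  if (length(cfg$ratios) == 0 || any(cfg$ratios <= 0 | cfg$ratios > 1))
    stop("config error: ratios must lie in (0, 1]")
  allowed <- c("proxy-input", "cnn3", "unet", "resunet", "tvmin")
  if (length(cfg$methods) == 0 || !all(cfg$methods %in% allowed))
    stop("config error: methods must be a non-empty subset of ",
         paste(allowed, collapse = ", "))
  if (cfg$trainFraction <= 0 || cfg$trainFraction >= 1)
    stop("config error: trainFraction must lie in (0, 1)")
  cfg
}

#' Load or save a benchmark configuration file
#'
#' Configurations are stored as YAML with exactly the keys documented in
#' [benchmarkConfig()]; unknown keys are an error listing the offenders.
#'
#' @param path YAML file path.
#' @return \code{loadConfig} returns a validated configuration list;
#'   \code{saveConfig} returns \code{path} invisibly.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config error: no such file: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config error: top level must be a mapping")
  do.call(benchmarkConfig, raw)
}

#' @rdname loadConfig
#' @param cfg configuration list from [benchmarkConfig()].
#' @export
saveConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

benchDataset <- function(cfg) {
  if (!is.null(cfg$datasetDir)) return(loadDataset(cfg$datasetDir))
  phantoms <- lapply(seq_len(cfg$nPhantoms), function(i)
    generatePhantom(cfg$sideLength, cfg$complexity, seed = cfg$seed + i))
  splitDataset(phantoms, cfg$trainFraction, seed = cfg$seed)
}

#' Run the end-to-end reconstruction benchmark
#'
#' Generates (or loads) the dataset, builds a Gaussian measurement matrix
#' per undersampling ratio, trains each learned method, runs the TV
#' baseline, evaluates SSIM/PSNR of every method on the test split, and
#' writes to \code{cfg$outputDir}:
#' \itemize{
#'   \item \code{records.csv}: one row per (image, method, ratio);
#'   \item \code{report.csv} and \code{report.json}: mean +/- SD per
#'     (method, ratio);
#'   \item \code{manifest.json}: config hash, package version, per-stage
#'     seeds and md5 checksums of all outputs.
#' }
#' The proxy-input baseline is always included, so each learned method's
#' improvement is measured against its own network input.  Two runs from
#' the same configuration produce byte-identical CSV reports.
#'
#' @param cfg configuration from [benchmarkConfig()] (must name
#'   \code{outputDir}).
#' @return list with \code{records}, \code{report} and \code{manifest}.
#' @export
runBenchmark <- function(cfg) {
  cfg <- benchmarkConfig(cfg[!vapply(cfg, is.null, logical(1))])
  if (is.null(cfg$outputDir)) stop("config error: outputDir is required")
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  stageSeeds <- list(dataset = cfg$seed, matrix = cfg$seed + 1000L,
                     training = cfg$seed + 2000L)
  logStage <- function(stage, ...)
    message(sprintf("[%s] %s", stage, sprintf(...)))

  stage <- "dataset"
  result <- tryCatch({
    split <- benchDataset(cfg)
    logStage(stage, "train=%d test=%d side=%d", length(split@train),
             length(split@test), sideLength(split@train[[1]]))
    n <- sideLength(split@train[[1]])
    learned <- intersect(cfg$methods, c("cnn3", "unet", "resunet"))
    records <- list()
    for (ri in seq_along(cfg$ratios)) {
      ratio <- cfg$ratios[ri]
      stage <- sprintf("matrix(ratio=%g)", ratio)
      K <- gaussianMatrix(n, ratio, seed = stageSeeds$matrix + ri)
      logStage(stage, "K %d x %d", nrow(entries(K)), ncol(entries(K)))
      if ("proxy-input" %in% cfg$methods)
        records[[length(records) + 1]] <- proxyBaselineRecords(K, split)
      for (fam in learned) {
        stage <- sprintf("train(%s, ratio=%g)", fam, ratio)
        spec <- networkSpec(fam, depth = cfg$depth,
                            baseChannels = cfg$baseChannels)
        model <- buildModel(spec, K, seed = stageSeeds$training + ri)
        tCfg <- trainConfig(learningRate = cfg$learningRate,
                            batchSize = cfg$batchSize,
                            epochs = cfg$epochs,
                            optimizer = cfg$optimizer,
                            seed = stageSeeds$training + 100L * ri)
        t0 <- proc.time()[["elapsed"]]
        model <- trainModel(model, split, tCfg)
        logStage(stage, "final loss %.5f (%.1fs)",
                 model@trainHistory$loss[nrow(model@trainHistory)],
                 proc.time()[["elapsed"]] - t0)
        recs <- evaluateOnSplit(model, split)
        records[[length(records) + 1]] <- recs
        if (cfg$writeImages) {
          x <- split@test[[1]]
          rec <- reconstruct(model, measure(K, x))
          writePhantom(rec, file.path(cfg$outputDir,
            sprintf("recon_%s_r%03d.png", fam, round(100 * ratio))))
        }
      }
      if ("tvmin" %in% cfg$methods) {
        stage <- sprintf("tvmin(ratio=%g)", ratio)
        rows <- lapply(seq_along(split@test), function(i) {
          x <- split@test[[i]]
          sol <- tvMinimize(K, measure(K, x), lambda = cfg$tvLambda,
                            maxIters = cfg$tvIters)
          metricRecord(sprintf("test_%04d", i), "tvmin", ratio,
                       ssim(sol@image, x), psnr(sol@image, x))
        })
        records[[length(records) + 1]] <- do.call(rbind, rows)
        logStage(stage, "done (%d images)", length(split@test))
      }
    }
    records <- do.call(rbind, records)
    report <- aggregateMetrics(records)
    list(records = records, report = report)
  }, error = function(e) {
    stop(sprintf("benchmark aborted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  recPath <- file.path(cfg$outputDir, "records.csv")
  repPath <- file.path(cfg$outputDir, "report.csv")
  jsonPath <- file.path(cfg$outputDir, "report.json")
  writeCsvCanonical(result$records, recPath)
  writeCsvCanonical(result$report, repPath)
  jsonlite::write_json(result$report, jsonPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  files <- c(recPath, repPath, jsonPath)
  manifest <- list(
    configHash = md5OfObject(cfg[order(names(cfg))]),
    packageVersion = as.character(utils::packageVersion("PATRecon")),
    stageSeeds = stageSeeds,
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(cfg$outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  result$manifest <- manifest
  result
}

# CSV writer with fixed numeric formatting so identical results are
# byte-identical on disk
writeCsvCanonical <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 12, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
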
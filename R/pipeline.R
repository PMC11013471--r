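# End-to-end orchestration: (simulate | read) -> filter -> impute -> prune ->
# marker-selection strategies -> validation, with every intermediate artifact
# written to the output directory and a JSON manifest recording the seed,
# the configuration and per-stage timings. Reruns with the same configuration
# reproduce all result files byte for byte (timings excepted).

.validateRunConfig <- function(config) {
  hasSim <- !is.null(config$simulate)
  hasPaths <- !is.null(config$genotypes)
  if (hasSim == hasPaths)
    stop("config must contain exactly one of 'simulate' or 'genotypes'/'phenotypes' paths",
         call. = FALSE)
  if (hasPaths && is.null(config$phenotypes))
    stop("'genotypes' requires a companion 'phenotypes' path", call. = FALSE)
  invisible(config)
}

.cfgGet <- function(config, key, default) {
  if (is.null(config[[key]])) default else config[[key]]
}

#' Run the full selective genotyping/phenotyping pipeline
#'
#' Stages, in order: load or simulate a population (with an external
#' validation split), marker quality filtering, mean imputation, LD pruning,
#' size-schedule construction, the requested marker-selection strategies with
#' cross-validation and external validation, and optionally the training-set
#' size sweep. Artifacts written to \code{outdir}: \code{pruned_markers.txt},
#' per-subset marker id lists under \code{subsets/},
#' \code{strategy_results.tsv}, optionally \code{ts_sweep.tsv}, and
#' \code{manifest.json}.
#'
#' @param config a named list (or path to a YAML file) with components:
#'   \code{simulate} (arguments to [simConfig()]) or \code{genotypes} /
#'   \code{phenotypes} (/ \code{map}) paths; optional \code{externalFraction}
#'   (default 0.1), \code{filter} (maxMissingProp, minMaf), \code{prune}
#'   (r2Threshold, windowSize), \code{schedule} (retentionFraction, minSize),
#'   \code{cv} (k, nRepetitions), \code{strategies}, \code{nRandomReps},
#'   \code{remobReps}, \code{coreFractions}, \code{runTsSweep}, \code{seed}.
#' @param outdir output directory (created if absent).
#' @param seed optional override of \code{config$seed}.
#' @return Invisibly, a list with the results tables and the manifest.
#' @export
runPipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  .validateRunConfig(config)
  if (!is.null(seed)) config$seed <- seed
  seed <- .cfgGet(config, "seed", 1L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  # --- load or simulate ------------------------------------------------
  pop <- clock("population", {
    if (!is.null(config$simulate)) {
      simArgs <- config$simulate
      simArgs$seed <- .substream(seed, "pipeline_sim")
      cfg <- do.call(simConfig, simArgs)
      G <- simulatePopulation(cfg)
      sim <- simulatePhenotype(G, cfg)
      list(G = sim$genotypes, y = sim$phenotype, truth = sim$truth)
    } else {
      G <- if (grepl("\\.vcf(\\.gz)?$", config$genotypes))
        readGenotypesVCF(config$genotypes)
      else readGenotypesTable(config$genotypes, mapPath = config$map)
      list(G = G, y = readPhenotypes(config$phenotypes), truth = NULL)
    }
  })
  # external validation split
  extFrac <- .cfgGet(config, "externalFraction", 0.1)
  n <- length(pop$y)
  nExt <- max(3L, as.integer(ceiling(n * extFrac - 0.5)))
  extIdx <- .withSeed(.substream(seed, "pipeline_split"),
                      sort(sample.int(n, nExt)))
  ids <- names(pop$y)
  GVal <- pop$G[ids[extIdx], ]
  yVal <- pop$y[extIdx]
  G <- pop$G[ids[-extIdx], ]
  y <- pop$y[-extIdx]

  # --- filter / impute / prune ----------------------------------------
  filt <- .cfgGet(config, "filter", list())
  G <- clock("filter", filterMarkers(G,
         maxMissingProp = .cfgGet(filt, "maxMissingProp", 0.8),
         minMaf = .cfgGet(filt, "minMaf", 0.05)))
  G <- clock("impute", imputeMean(G))
  pr <- .cfgGet(config, "prune", list())
  G <- clock("prune", pruneLD(G,
         r2Threshold = .cfgGet(pr, "r2Threshold", 0.95),
         windowSize = .cfgGet(pr, "windowSize", 100)))
  GVal <- GVal[, markerIds(G)]
  GVal <- imputeMean(GVal)
  writeLines(markerIds(G), file.path(outdir, "pruned_markers.txt"))

  # --- schedule and strategies ----------------------------------------
  sch <- .cfgGet(config, "schedule", list())
  sizes <- scheduleSizes(nMarkers(G),
                         retentionFraction = .cfgGet(sch, "retentionFraction", 0.30),
                         minSize = .cfgGet(sch, "minSize", 48))
  sizes <- restrictSchedule(sizes, nMarkers(G))
  cvCfg <- .cfgGet(config, "cv", list())
  results <- clock("strategies", runStrategyComparison(
    G, y, GVal, yVal, sizes,
    strategies = .cfgGet(config, "strategies",
                         c("NRE_MB", "NRE_R", "RE_MAB", "RE_MOB")),
    k = .cfgGet(cvCfg, "k", 10),
    nRepetitions = .cfgGet(cvCfg, "nRepetitions", 20),
    nRandomReps = .cfgGet(config, "nRandomReps", 100),
    remobReps = .cfgGet(config, "remobReps", 100),
    seed = .substream(seed, "pipeline_strategies"),
    populationLabel = .cfgGet(config, "populationLabel", "pop")))
  utils::write.table(results, file.path(outdir, "strategy_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  subsetsDir <- file.path(outdir, "subsets")
  dir.create(subsetsDir, showWarnings = FALSE)
  fitFull <- fitRRBLUP(G, y)
  for (sub in selectNREMB(fitFull, sizes))
    writeLines(sub@markerIds,
               file.path(subsetsDir, sprintf("nre_mb_%d.txt", sub@size)))

  sweep <- NULL
  if (isTRUE(.cfgGet(config, "runTsSweep", FALSE))) {
    sweep <- clock("ts_sweep", runTSSizeSweep(
      G, y, GVal, yVal,
      fractions = .cfgGet(config, "coreFractions",
                          c(0.75, 0.5, 0.2, 0.1, 0.05)),
      nRandomReps = .cfgGet(config, "nRandomReps", 20),
      k = .cfgGet(cvCfg, "k", 10),
      nRepetitions = .cfgGet(cvCfg, "nRepetitions", 20),
      seed = .substream(seed, "pipeline_sweep"),
      populationLabel = .cfgGet(config, "populationLabel", "pop")))
    utils::write.table(sweep, file.path(outdir, "ts_sweep.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    seed = seed, config = config,
    nGenotypesTrain = length(y), nGenotypesExternal = length(yVal),
    nMarkersPruned = nMarkers(G), schedule = as.list(sizes),
    timingsSec = as.list(timings),
    packageVersion = as.character(utils::packageVersion("selectGS")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, sweep = sweep, manifest = manifest,
                 genotypes = G, phenotypes = y))
}
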
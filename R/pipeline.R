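#' @include AllClasses.R
NULL

.defaultRunConfig <- function() {
  list(
    seed = 1L,
    genotype = "WT",
    meioses = 1L,
    snpMap = NULL,      # path; simulated when NULL
    counts = NULL,      # path; start at genotype calling when given
    octad = NULL,       # path; start at event inference when given
    depth = 70,
    errorRate = 0,
    convention = "mid",
    sim = list(),       # overrides for SimParams()
    call = list(),      # overrides for GenotypeCallConfig()
    infer = list()      # overrides for InferenceConfig()
  )
}

#' Read a pipeline configuration
#'
#' A single YAML document mirroring the run configuration: seed, genotype
#' label, number of meioses, optional input paths (`snpMap`, `counts`,
#' `octad`), sequencing depth and error rate, length convention, and nested
#' overrides `sim`, `call`, `infer` for [SimParams()],
#' [GenotypeCallConfig()] and [InferenceConfig()].
#'
#' @param path YAML file path.
#'
#' @return A named list (defaults filled in).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- .defaultRunConfig()
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg
}

.applyOverrides <- function(constructor, overrides) {
  overrides <- overrides[!vapply(overrides, is.null, logical(1L))]
  if (!is.null(overrides$chromLengths))
    overrides$chromLengths <- unlist(overrides$chromLengths)
  do.call(constructor, overrides)
}

#' Run the full octad analysis pipeline
#'
#' Composes `simulate -> call -> infer -> stats` (stages are skipped from the
#' left when a counts or octad file is supplied). Artifacts are written to
#' `outDir`: the SNP map, per-meiosis octad matrices and ground truth (when
#' simulating), the inferred events (BED-flavoured TSV), a JSON summary
#' including per-genotype interference fits, and a machine-readable JSON run
#' log recording the seed and every threshold applied. Deterministic for a
#' fixed seed.
#'
#' @param config A configuration list (see [readRunConfig()]) or a path to a
#'   YAML file.
#' @param outDir Output directory (created if needed).
#'
#' @return Invisibly, a list with the [EventSet()], the summary list, the
#'   [GammaFit()]s per genotype, and the paths of all artifacts.
#' @export
#' @examples
#' cfg <- list(seed = 1, meioses = 1,
#'             sim = list(chromLengths = list(chr1 = 2e5)))
#' res <- runPipeline(cfg, outDir = tempfile("run"))
#' res$summary$counts
runPipeline <- function(config = list(), outDir = "octad_run") {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- .defaultRunConfig()
  for (k in names(config)) cfg[[k]] <- config[[k]]
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  simParams <- stage("config", .applyOverrides(SimParams, cfg$sim))
  callCfg <- stage("config", .applyOverrides(GenotypeCallConfig, cfg$call))
  inferCfg <- stage("config", .applyOverrides(InferenceConfig, cfg$infer))
  paths <- list()

  ## --- inputs ---------------------------------------------------------
  octads <- list()
  if (!is.null(cfg$octad)) {
    map <- if (!is.null(cfg$snpMap)) stage("read_snp_map", readSnpMap(cfg$snpMap))
           else NULL
    octads[["m1"]] <- stage("read_octad", readOctad(cfg$octad, map))
  } else if (!is.null(cfg$counts)) {
    if (is.null(cfg$snpMap))
      stop("pipeline stage 'read_counts' failed: counts input requires snpMap")
    map <- stage("read_snp_map", readSnpMap(cfg$snpMap))
    counts <- stage("read_counts", readCounts(cfg$counts, map))
    octads[["m1"]] <- stage("call", callMatrix(counts, callCfg))
  } else {
    map <- if (!is.null(cfg$snpMap)) stage("read_snp_map", readSnpMap(cfg$snpMap))
           else stage("simulate", buildSnpMap(simParams@chromLengths,
                                              simParams@snpDensity,
                                              seed = cfg$seed))
    paths$snpMap <- file.path(outDir, "snp_map.tsv")
    writeSnpMap(map, paths$snpMap)
    for (i in seq_len(cfg$meioses)) {
      mid <- sprintf("m%d", i)
      sim <- stage("simulate",
                   simulateMeiosis(map, simParams,
                                   seed = childSeed(cfg$seed, 1000L + i)))
      counts <- stage("simulate",
                      emitReadCounts(sim$octad, depth = cfg$depth,
                                     errorRate = cfg$errorRate,
                                     seed = childSeed(cfg$seed, 2000L + i)))
      octads[[mid]] <- stage("call", callMatrix(counts, callCfg))
      truthPath <- file.path(outDir, sprintf("truth_%s.tsv", mid))
      utils::write.table(sim$truth, truthPath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      octPath <- file.path(outDir, sprintf("octad_%s.tsv", mid))
      writeOctad(octads[[mid]], octPath)
      paths[[paste0("octad_", mid)]] <- octPath
      paths[[paste0("truth_", mid)]] <- truthPath
    }
  }

  ## --- inference ------------------------------------------------------
  evList <- lapply(names(octads), function(mid)
    stage("infer", inferEvents(octads[[mid]], inferCfg, meiosis = mid,
                               genotype = cfg$genotype))@events)
  ev <- do.call(rbind, evList)
  lens <- if (length(octads)) octads[[1L]]@map@chromLengths else numeric()
  eventSet <- new("EventSet", events = ev, chromLengths = lens)
  paths$events <- file.path(outDir, "events.tsv")
  writeEvents(eventSet, paths$events)

  ## --- statistics -----------------------------------------------------
  summary <- stage("stats", summarizeEvents(eventSet, cfg$convention))
  gaps <- interCoDistances(eventSet)
  fits <- if (nrow(gaps)) tryCatch(fitInterference(gaps), error = function(e) list())
          else list()
  summary$interference <- lapply(fits, function(f)
    list(shape = round(f@shape, 1), scale = f@scale, nGaps = f@nGaps,
         loglik = f@loglik))
  paths$summary <- file.path(outDir, "summary.json")
  writeSummary(summary, paths$summary)

  ## --- run log --------------------------------------------------------
  log <- list(
    package = "octadRecomb",
    version = as.character(utils::packageVersion("octadRecomb")),
    seed = cfg$seed, genotype = cfg$genotype, meioses = length(octads),
    depth = cfg$depth, errorRate = cfg$errorRate,
    convention = cfg$convention,
    genotypeCall = list(monoMin = callCfg@monoMin, monoMax = callCfg@monoMax,
                        duoMajorMin = callCfg@duoMajorMin,
                        duoMajorMax = callCfg@duoMajorMax,
                        duoMinorLt = callCfg@duoMinorLt),
    inference = list(mergeGapBp = inferCfg@mergeGapBp,
                     maxMissingRun = inferCfg@maxMissingRun,
                     minMarkersPerTract = inferCfg@minMarkersPerTract,
                     minPhaseBlockBp = inferCfg@minPhaseBlockBp),
    sim = list(gammaShape = simParams@gammaShape,
               meanInterCo = simParams@meanInterCo,
               ncoRate = simParams@ncoRate,
               snpDensity = simParams@snpDensity,
               tractLenDist = simParams@tractLenDist,
               pTransHdna = simParams@pTransHdna,
               pSymHdna = simParams@pSymHdna,
               mmrActive = simParams@mmrActive))
  paths$log <- file.path(outDir, "run_log.json")
  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(events = eventSet, summary = summary, interference = fits,
                 paths = paths))
}
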
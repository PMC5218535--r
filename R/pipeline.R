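#' @include AllClasses.R io.R simulate-widefield.R fourier.R fieldsign.R coverage.R
NULL

cfgApply <- function(constructor, values) {
  if (is.null(values)) return(constructor())
  do.call(constructor, values)
}

#' Run the retinotopic-mapping pipeline from a configuration
#'
#' Executes simulate (unless movies are supplied) -> delta F / phase maps ->
#' field-sign segmentation -> coverage, writing all artifacts and a JSON
#' run report (parameter echo, seed, per-stage timings, patch summary) to
#' the output directory.  Deterministic for a fixed configuration and seed.
#'
#' @param cfg configuration list (see \code{\link{readRunConfig}}), or a
#'   path to a YAML file.
#' @param quiet suppress per-stage progress messages.
#' @return The run report, invisibly.
#' @export
runPipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message("[retinomap] ", ...)
  outDir <- cfg$outputDir
  stopIfNot(!is.null(outDir), "config must set outputDir")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(cfg$seed)) cfg$seed else 1L
  timings <- list()
  stage <- function(name, expr) {
    s <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    say(name, " done (", sprintf("%.1f", timings[[name]]), " s)")
    r
  }
  atlasArgs <- cfg$atlas
  atlas <- stage("atlas", cfgApply(buildDefaultAtlas, atlasArgs))
  simCfgArgs <- cfg$simulation
  if (is.null(simCfgArgs$seed)) simCfgArgs$seed <- seed
  simCfg <- cfgApply(SimulationConfig, simCfgArgs)
  spec <- cfgApply(CheckerboardSpec, cfg$stimulus)
  geom <- cfgApply(MonitorGeometry, cfg$monitor)
  movies <- if (!is.null(cfg$inputs$movies)) {
    stage("load", lapply(cfg$inputs$movies, readMovieTiff))
  } else {
    stage("simulate", simulateMappingSession(atlas, spec = spec,
                                             geom = geom, config = simCfg))
  }
  phaseArgs <- cfg$phase
  maps <- stage("phase", do.call(extractPositionMaps,
                                 c(list(movies), phaseArgs)))
  params <- cfgApply(SegmentationParams, cfg$segmentation)
  pm <- stage("segment", segmentPatches(maps, params))
  if (nrow(pm@patches) == 0)
    warning("segmentation produced no patches; check the sign threshold")
  res <- if (!is.null(cfg$coverage$resolutionDeg))
    cfg$coverage$resolutionDeg else 1
  cov <- stage("coverage", coverageByPatch(pm, maps, res))
  stage("write", {
    saveMaps(maps, file.path(outDir, "maps"))
    savePatchMap(pm, file.path(outDir, "patchmap"))
    utils::write.csv(cov$summary, file.path(outDir, "coverage.csv"),
                     row.names = FALSE)
  })
  report <- list(
    seed = seed,
    parameters = list(atlas = atlasArgs,
                      simulation = simCfgArgs,
                      segmentation = cfg$segmentation,
                      phase = phaseArgs),
    nPatches = nrow(pm@patches),
    patchSigns = pm@patches$sign,
    patchPixels = pm@patches$nPixels,
    coverageDeg2 = cov$summary$areaDeg2,
    timingsS = timings,
    totalS = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
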
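#' @include AllClasses.R utils.R
NULL

writeMatrixCsv <- function(m, path)
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)

readMatrixCsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  m
}

#' Save / load position maps as a plain-text directory
#'
#' Maps are stored as CSV matrices (altitude, azimuth, amplitude, validity)
#' with a JSON metadata file recording the class, shape, pixel size and the
#' row/column convention (rows increase posterior, columns lateral;
#' zero-based half-open pixel ranges in all serialized coordinates).
#'
#' @param maps a \linkS4class{PositionMaps}.
#' @param dir target directory (created if needed).
#' @return \code{saveMaps} returns \code{dir} invisibly; \code{loadMaps}
#'   returns the restored \linkS4class{PositionMaps}.
#' @export
saveMaps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(class = "PositionMaps", dims = dim(maps@altitude),
               pixelSizeUm = maps@pixelSizeUm,
               convention = "row=posterior, col=lateral, 0-based half-open")
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  writeMatrixCsv(maps@altitude, file.path(dir, "altitude.csv"))
  writeMatrixCsv(maps@azimuth, file.path(dir, "azimuth.csv"))
  writeMatrixCsv(maps@amplitude, file.path(dir, "amplitude.csv"))
  writeMatrixCsv(maps@valid * 1, file.path(dir, "valid.csv"))
  invisible(dir)
}

#' @rdname saveMaps
#' @export
loadMaps <- function(dir) {
  metaPath <- file.path(dir, "meta.json")
  stopIfNot(file.exists(metaPath), paste("no metadata at", metaPath))
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  stopIfNot(identical(meta$class, "PositionMaps"),
            "directory does not hold PositionMaps")
  alt <- readMatrixCsv(file.path(dir, "altitude.csv"))
  azi <- readMatrixCsv(file.path(dir, "azimuth.csv"))
  amp <- readMatrixCsv(file.path(dir, "amplitude.csv"))
  val <- readMatrixCsv(file.path(dir, "valid.csv")) > 0.5
  stopIfNot(identical(dim(alt), as.integer(meta$dims)),
            "altitude map shape does not match metadata")
  PositionMaps(alt, azi, amp, val,
               pixelSizeUm = as.numeric(meta$pixelSizeUm))
}

#' Save / load a patch map
#'
#' The label image goes to CSV; patch metadata, borders (as zero-based
#' pixel polyline coordinates in cortical micrometers) and the pixel size
#' go to JSON.
#'
#' @param pm a \linkS4class{PatchMap}.
#' @param dir target directory.
#' @return \code{savePatchMap} returns \code{dir} invisibly;
#'   \code{loadPatchMap} the restored \linkS4class{PatchMap}.
#' @export
savePatchMap <- function(pm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  px <- if (is.finite(pm@pixelSizeUm)) pm@pixelSizeUm else 1
  meta <- list(class = "PatchMap", dims = dim(pm@labels),
               pixelSizeUm = pm@pixelSizeUm,
               patches = pm@patches,
               bordersUm = if (nrow(pm@borders))
                 (pm@borders - 1) * px else matrix(0, 0, 2))
  jsonlite::write_json(meta, file.path(dir, "patchmap.json"),
                       auto_unbox = TRUE, digits = NA)
  writeMatrixCsv(pm@labels, file.path(dir, "labels.csv"))
  writeMatrixCsv(pm@raw, file.path(dir, "raw.csv"))
  invisible(dir)
}

#' @rdname savePatchMap
#' @export
loadPatchMap <- function(dir) {
  metaPath <- file.path(dir, "patchmap.json")
  stopIfNot(file.exists(metaPath), paste("no metadata at", metaPath))
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  stopIfNot(identical(meta$class, "PatchMap"),
            "directory does not hold a PatchMap")
  L <- readMatrixCsv(file.path(dir, "labels.csv"))
  L <- matrix(as.integer(L), nrow(L), ncol(L))
  raw <- readMatrixCsv(file.path(dir, "raw.csv"))
  patches <- as.data.frame(meta$patches)
  if (!nrow(patches))
    patches <- data.frame(id = integer(0), sign = integer(0),
                          nPixels = integer(0), name = character(0))
  patches$id <- as.integer(patches$id)
  patches$sign <- as.integer(patches$sign)
  patches$nPixels <- as.integer(patches$nPixels)
  if (is.null(patches$name)) patches$name <- NA_character_
  px <- as.numeric(meta$pixelSizeUm)
  b <- borderPixels(L)
  new("PatchMap", labels = L, patches = patches, raw = raw, borders = b,
      pixelSizeUm = px)
}

#' Write a movie as a multi-page TIFF with JSON metadata
#'
#' Frames of the trial-mean movie are normalized to [0, 1] for TIFF
#' storage; the scale and offset, frame rate, onset and trajectory are
#' recorded in a sidecar JSON so the movie round-trips.
#'
#' @param movie a \linkS4class{Movie}.
#' @param path output TIFF path; metadata goes to \code{paste0(path,
#'   ".json")}.
#' @return \code{writeMovieTiff} returns \code{path} invisibly;
#'   \code{readMovieTiff} the restored single-trial \linkS4class{Movie}.
#' @export
writeMovieTiff <- function(movie, path) {
  m <- colMeans(movie@data, dims = 1)
  lo <- min(m); hi <- max(m)
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(dim(m)[1]), function(i) (m[i, , ] - lo) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32, reduce = FALSE)
  traj <- movie@trajectory
  meta <- list(class = "Movie", offset = lo, scale = scale,
               frameRate = movie@frameRate, direction = movie@direction,
               onsetS = movie@onsetS, kind = movie@kind,
               pixelSizeUm = movie@pixelSizeUm,
               trajectory = list(axis = traj@axis,
                                 direction = traj@direction,
                                 startDeg = traj@startDeg,
                                 speedDegPerS = traj@speedDegPerS,
                                 periodS = traj@periodS,
                                 sweepDurationS = traj@sweepDurationS))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeMovieTiff
#' @export
readMovieTiff <- function(path) {
  metaPath <- paste0(path, ".json")
  stopIfNot(file.exists(metaPath), paste("no metadata at", metaPath))
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  stopIfNot(identical(meta$class, "Movie"), "not a movie TIFF")
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(1, length(frames), dim(frames[[1]])[1:2]))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (length(dim(f)) == 3) f <- f[, , 1]
    arr[1, i, , ] <- f * meta$scale + meta$offset
  }
  tj <- meta$trajectory
  traj <- new("BarTrajectory", axis = tj$axis, direction = tj$direction,
              startDeg = tj$startDeg, speedDegPerS = tj$speedDegPerS,
              periodS = tj$periodS, sweepDurationS = tj$sweepDurationS)
  new("Movie", data = arr, frameRate = meta$frameRate,
      direction = meta$direction, onsetS = meta$onsetS, trajectory = traj,
      kind = meta$kind, pixelSizeUm = as.numeric(meta$pixelSizeUm))
}

#' Save / load a coverage mask
#'
#' @param mask a \linkS4class{CoverageMask}.
#' @param dir target directory.
#' @return \code{saveCoverageMask} returns \code{dir} invisibly;
#'   \code{loadCoverageMask} the restored mask.
#' @export
saveCoverageMask <- function(mask, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(class = "CoverageMask",
                            resolutionDeg = mask@resolutionDeg,
                            extentDeg = mask@extentDeg),
                       file.path(dir, "coverage.json"), auto_unbox = TRUE,
                       digits = NA)
  writeMatrixCsv(mask@grid * 1, file.path(dir, "grid.csv"))
  invisible(dir)
}

#' @rdname saveCoverageMask
#' @export
loadCoverageMask <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "coverage.json"),
                              simplifyVector = TRUE)
  stopIfNot(identical(meta$class, "CoverageMask"), "not a coverage mask")
  new("CoverageMask", grid = readMatrixCsv(file.path(dir, "grid.csv")) > 0.5,
      resolutionDeg = as.numeric(meta$resolutionDeg),
      extentDeg = as.numeric(meta$extentDeg))
}

## Allowed run-config keys (nested), mirroring the manually set variables
## of the analysis routine.
runConfigSchema <- function() {
  list(
    seed = NULL, outputDir = NULL,
    atlas = c("dims", "pixelSizeUm", "v1Only"),
    stimulus = c("barWidthDeg", "squareSizeDeg", "flickerHz",
                 "sweepSpeedDegPerS", "interSweepGapS",
                 "backgroundLuminance", "repeatFreqAzimuthHz",
                 "repeatFreqAltitudeHz", "nSweepsPerDirection"),
    monitor = c("distanceCm", "midlineAngleDeg", "azimuthExtentDeg",
                "altitudeExtentDeg"),
    simulation = c("frameRateHz", "pixelSizeUm", "noiseSd", "riseS",
                   "decayS", "photobleachCoeff", "illumination",
                   "responseAmplitude", "baselineWindowS", "nCycles",
                   "seed"),
    phase = c("minAmplitudeFrac", "detrend"),
    segmentation = c("signFilterSigmaUm", "signThreshold",
                     "redundancyThreshold", "minPatchPixels",
                     "openCloseRadiusPx", "borderWidthPx",
                     "coverageResolutionDeg", "watershedProminenceDeg",
                     "maxIter", "growthIter"),
    coverage = c("resolutionDeg"),
    pupil = c("roiRowMin", "roiRowMax", "roiColMin", "roiColMax",
              "pxSizeMm", "eyeRadiusMm"),
    inputs = c("movies", "maps", "patchMap"))
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected (catching typos in the thirteen manually set
#' segmentation variables); any referenced input paths must exist.
#'
#' @param path YAML file path.
#' @return A named list of configuration sections.
#' @export
readRunConfig <- function(path) {
  stopIfNot(file.exists(path), paste("config not found:", path))
  cfg <- yaml::read_yaml(path)
  schema <- runConfigSchema()
  bad <- setdiff(names(cfg), names(schema))
  stopIfNot(length(bad) == 0,
            paste("unknown config keys:", paste(bad, collapse = ", ")))
  for (sec in names(cfg)) {
    allowed <- schema[[sec]]
    if (is.null(allowed)) next
    badSub <- setdiff(names(cfg[[sec]]), allowed)
    stopIfNot(length(badSub) == 0,
              paste0("unknown keys in '", sec, "': ",
                     paste(badSub, collapse = ", ")))
  }
  for (p in unlist(cfg$inputs))
    stopIfNot(file.exists(p), paste("referenced input does not exist:", p))
  cfg
}

#' Write a run configuration
#'
#' @param cfg configuration list.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
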
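#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Stimulus geometry
## ---------------------------------------------------------------------------

#' Monitor geometry for visual stimulation
#'
#' Describes the planar stimulus monitor relative to the eye.  The eye sits at
#' the origin; the perpendicular from the eye meets the monitor at distance
#' \code{distanceCm}.  With the animal's midline at \code{midlineAngleDeg} to
#' the monitor plane, the perpendicular points at azimuth
#' \code{90 - midlineAngleDeg} (60 degrees for the default 30-degree
#' placement) and altitude 0.
#'
#' @slot distanceCm eye-to-screen perpendicular distance (cm).
#' @slot midlineAngleDeg angle of the midline to the monitor plane (degrees).
#' @slot azimuthExtentDeg length-2 numeric, azimuth range covered (degrees).
#' @slot altitudeExtentDeg length-2 numeric, altitude range covered (degrees).
#' @export
setClass("MonitorGeometry",
  representation(distanceCm = "numeric", midlineAngleDeg = "numeric",
                 azimuthExtentDeg = "numeric", altitudeExtentDeg = "numeric"),
  prototype(distanceCm = 13.5, midlineAngleDeg = 30,
            azimuthExtentDeg = c(-10, 130), altitudeExtentDeg = c(-50, 60)),
  validity = function(object) {
    msg <- NULL
    if (length(object@distanceCm) != 1 || object@distanceCm <= 0)
      msg <- c(msg, "distanceCm must be a single positive number")
    for (s in c("azimuthExtentDeg", "altitudeExtentDeg")) {
      e <- slot(object, s)
      if (length(e) != 2 || !all(is.finite(e)) || e[1] >= e[2])
        msg <- c(msg, paste(s, "must be an ordered (min < max) pair"))
    }
    if (is.null(msg)) TRUE else msg
  })

#' @rdname MonitorGeometry-class
#' @param distanceCm,midlineAngleDeg,azimuthExtentDeg,altitudeExtentDeg see slots.
#' @return A \code{MonitorGeometry} object.
#' @examples
#' geom <- MonitorGeometry()
#' sphericalCorrect(0, 0, geom)   # perpendicular point: altitude 0, azimuth 60
#' @export
MonitorGeometry <- function(distanceCm = 13.5, midlineAngleDeg = 30,
                            azimuthExtentDeg = c(-10, 130),
                            altitudeExtentDeg = c(-50, 60)) {
  new("MonitorGeometry", distanceCm = distanceCm,
      midlineAngleDeg = midlineAngleDeg,
      azimuthExtentDeg = as.numeric(azimuthExtentDeg),
      altitudeExtentDeg = as.numeric(altitudeExtentDeg))
}

#' Drifting-checkerboard stimulus parameters
#'
#' Defaults follow the standard periodic mapping stimulus: a 20-degree bar
#' filled with a 25-degree checkerboard counterphasing at 6 Hz, sweeping at
#' 9 deg/s, repeating at 0.043 Hz (horizontal sweeps, azimuth) or 0.048 Hz
#' (vertical sweeps, altitude); residual time within the repetition period
#' beyond the sweep itself is an inter-sweep gap with the bar off screen.
#'
#' @slot barWidthDeg bar width along the direction of propagation (degrees).
#' @slot squareSizeDeg checker square size (degrees).
#' @slot flickerHz counterphase rate of the checker squares (Hz).
#' @slot sweepSpeedDegPerS drift speed (deg/s).
#' @slot interSweepGapS minimum gap between sweeps (s).
#' @slot backgroundLuminance background in [0, 1] (0.5 = mean-luminance grey).
#' @slot repeatFreqAzimuthHz,repeatFreqAltitudeHz stimulus repetition
#'   frequencies for horizontal and vertical sweeps (Hz); these are primary
#'   and define the sweep period directly.
#' @slot nSweepsPerDirection number of sweep repetitions per direction.
#' @export
setClass("CheckerboardSpec",
  representation(barWidthDeg = "numeric", squareSizeDeg = "numeric",
                 flickerHz = "numeric", sweepSpeedDegPerS = "numeric",
                 interSweepGapS = "numeric", backgroundLuminance = "numeric",
                 repeatFreqAzimuthHz = "numeric",
                 repeatFreqAltitudeHz = "numeric",
                 nSweepsPerDirection = "numeric"),
  validity = function(object) {
    msg <- NULL
    pos <- c("barWidthDeg", "squareSizeDeg", "flickerHz", "sweepSpeedDegPerS",
             "repeatFreqAzimuthHz", "repeatFreqAltitudeHz",
             "nSweepsPerDirection")
    for (s in pos) if (slot(object, s) <= 0)
      msg <- c(msg, paste(s, "must be > 0"))
    if (object@backgroundLuminance < 0 || object@backgroundLuminance > 1)
      msg <- c(msg, "backgroundLuminance must lie in [0, 1]")
    if (object@interSweepGapS < 0)
      msg <- c(msg, "interSweepGapS must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname CheckerboardSpec-class
#' @param barWidthDeg,squareSizeDeg,flickerHz,sweepSpeedDegPerS see slots.
#' @param interSweepGapS,backgroundLuminance see slots.
#' @param repeatFreqAzimuthHz,repeatFreqAltitudeHz,nSweepsPerDirection see slots.
#' @return A \code{CheckerboardSpec}.
#' @export
CheckerboardSpec <- function(barWidthDeg = 20, squareSizeDeg = 25,
                             flickerHz = 6, sweepSpeedDegPerS = 9,
                             interSweepGapS = 5, backgroundLuminance = 0.5,
                             repeatFreqAzimuthHz = 0.043,
                             repeatFreqAltitudeHz = 0.048,
                             nSweepsPerDirection = 10) {
  new("CheckerboardSpec", barWidthDeg = barWidthDeg,
      squareSizeDeg = squareSizeDeg, flickerHz = flickerHz,
      sweepSpeedDegPerS = sweepSpeedDegPerS, interSweepGapS = interSweepGapS,
      backgroundLuminance = backgroundLuminance,
      repeatFreqAzimuthHz = repeatFreqAzimuthHz,
      repeatFreqAltitudeHz = repeatFreqAltitudeHz,
      nSweepsPerDirection = nSweepsPerDirection)
}

#' Sparse-noise stimulus parameters
#'
#' Black and white squares flashed on a 50 percent grey background in
#' pseudorandom order; every grid location appears exactly
#' \code{repeatsPerPolarity} times for each polarity.
#'
#' @slot squareSizeDeg square side (degrees).
#' @slot durationS on-screen duration of one square (s).
#' @slot repeatsPerPolarity repetitions of each location/polarity pair.
#' @slot gridExtentDeg numeric length-4: azimuth min/max, altitude min/max.
#' @export
setClass("SparseNoiseSpec",
  representation(squareSizeDeg = "numeric", durationS = "numeric",
                 repeatsPerPolarity = "numeric", gridExtentDeg = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@squareSizeDeg <= 0) msg <- c(msg, "squareSizeDeg must be > 0")
    if (object@repeatsPerPolarity < 1)
      msg <- c(msg, "repeatsPerPolarity must be >= 1")
    if (object@durationS <= 0) msg <- c(msg, "durationS must be > 0")
    e <- object@gridExtentDeg
    if (length(e) != 4 || e[1] >= e[2] || e[3] >= e[4])
      msg <- c(msg, "gridExtentDeg must be c(aziMin, aziMax, altMin, altMax)")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname SparseNoiseSpec-class
#' @param squareSizeDeg,durationS,repeatsPerPolarity,gridExtentDeg see slots.
#' @return A \code{SparseNoiseSpec}.
#' @export
SparseNoiseSpec <- function(squareSizeDeg = 6, durationS = 0.1,
                            repeatsPerPolarity = 60,
                            gridExtentDeg = c(-6, 60, -24, 54)) {
  new("SparseNoiseSpec", squareSizeDeg = squareSizeDeg, durationS = durationS,
      repeatsPerPolarity = repeatsPerPolarity,
      gridExtentDeg = as.numeric(gridExtentDeg))
}

#' Bar-center trajectory of one sweep direction
#'
#' Linear-in-time bar position within each repetition period.  The bar center
#' moves from \code{startDeg} at \code{speedDegPerS} (signed) for
#' \code{sweepDurationS}; for the rest of the period the bar is off screen.
#'
#' @slot axis "azimuth" or "altitude".
#' @slot direction one of "N2T", "T2N", "D2U", "U2D".
#' @slot startDeg bar-center position at sweep onset (degrees).
#' @slot speedDegPerS signed drift speed (deg/s).
#' @slot periodS repetition period (s), 1/repeat frequency.
#' @slot sweepDurationS time the bar is on screen each period (s).
#' @export
setClass("BarTrajectory",
  representation(axis = "character", direction = "character",
                 startDeg = "numeric", speedDegPerS = "numeric",
                 periodS = "numeric", sweepDurationS = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@axis %in% c("azimuth", "altitude"))
      msg <- c(msg, "axis must be 'azimuth' or 'altitude'")
    if (object@periodS <= 0) msg <- c(msg, "periodS must be > 0")
    if (object@sweepDurationS <= 0 || object@sweepDurationS > object@periodS)
      msg <- c(msg, "sweepDurationS must lie in (0, periodS]")
    if (object@speedDegPerS == 0) msg <- c(msg, "speedDegPerS must be nonzero")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "BarTrajectory", function(object) {
  cat(sprintf(
    "BarTrajectory: %s sweep (%s), %g deg at t=0, %+g deg/s, period %.2f s (sweep %.2f s)\n",
    object@axis, object@direction, object@startDeg, object@speedDegPerS,
    object@periodS, object@sweepDurationS))
})

## ---------------------------------------------------------------------------
## Synthetic cortex
## ---------------------------------------------------------------------------

#' Ground-truth cortical atlas for simulation
#'
#' A set of named, disjoint cortical regions, each carrying an invertible
#' affine retinotopic transform from cortical pixel coordinates (col, row) to
#' visual coordinates (azimuth, altitude).  The ground-truth field sign of an
#' area is the sign of the determinant of the linear part of its transform
#' (negative for V1-like non-mirror maps under the package convention).
#'
#' @slot dims image dimensions c(rows, cols).
#' @slot pixelSizeUm cortical pixel size (micrometers).
#' @slot areas named list; each element has \code{mask} (logical matrix),
#'   \code{transform} (2x3 matrix mapping c(col, row, 1) to
#'   c(azimuth, altitude)) and \code{amplitude} (relative response amplitude).
#' @export
setClass("CorticalAtlas",
  representation(dims = "integer", pixelSizeUm = "numeric", areas = "list"),
  validity = function(object) {
    msg <- NULL
    occ <- matrix(0L, object@dims[1], object@dims[2])
    for (nm in names(object@areas)) {
      a <- object@areas[[nm]]
      if (!all(c("mask", "transform", "amplitude") %in% names(a)))
        msg <- c(msg, paste0("area '", nm, "' missing mask/transform/amplitude"))
      else {
        if (!identical(dim(a$mask), as.integer(object@dims)))
          msg <- c(msg, paste0("area '", nm, "' mask has wrong dimensions"))
        if (abs(det(a$transform[, 1:2])) < 1e-12)
          msg <- c(msg, paste0("area '", nm, "' transform is singular"))
        occ <- occ + a$mask
      }
    }
    if (any(occ > 1)) msg <- c(msg, "area regions overlap")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "CorticalAtlas", function(object) {
  cat(sprintf("CorticalAtlas: %d x %d px (%.1f um/px), %d areas\n",
              object@dims[1], object@dims[2], object@pixelSizeUm,
              length(object@areas)))
  sg <- fieldSign(object)
  for (nm in names(object@areas))
    cat(sprintf("  %-6s sign %+d  %5d px\n", nm, sg[[nm]],
                sum(object@areas[[nm]]$mask)))
})

#' @rdname CorticalAtlas-class
#' @param x a \code{CorticalAtlas}.
#' @export
setMethod("fieldSign", "CorticalAtlas", function(x) {
  vapply(x@areas, function(a) as.integer(sign(det(a$transform[, 1:2]))),
         integer(1))
})

#' @rdname CorticalAtlas-class
#' @export
setMethod("labelImage", "CorticalAtlas", function(x) {
  lab <- matrix(0L, x@dims[1], x@dims[2])
  for (i in seq_along(x@areas)) lab[x@areas[[i]]$mask] <- i
  lab
})

#' Widefield acquisition / simulation parameters
#'
#' Defaults reproduce the reference acquisition: 10 Hz frame rate, 12.9 um
#' effective pixels (2x2 binning), a fluorescence response kernel with 70 ms
#' rise and 540 ms decay, and linear photobleaching of 235 percent per
#' J/mm^2 at 89 uW/mm^2 illumination (0.02 percent per second).
#'
#' @slot frameRateHz acquisition rate (Hz).
#' @slot pixelSizeUm effective pixel size (um).
#' @slot noiseSd additive noise SD as a fraction of baseline fluorescence.
#' @slot riseS,decayS time constants of the difference-of-exponentials
#'   response kernel (s).
#' @slot photobleachCoeff bleaching coefficient (percent per J/mm^2).
#' @slot illumination illumination intensity (uW/mm^2).
#' @slot responseAmplitude peak fractional fluorescence response of a fully
#'   driven pixel (delta F over F).
#' @slot baselineWindowS pre-stimulus baseline recorded before onset (s).
#' @slot nCycles number of stimulus repetition periods simulated.
#' @slot seed integer seed for the noise generator.
#' @export
setClass("SimulationConfig",
  representation(frameRateHz = "numeric", pixelSizeUm = "numeric",
                 noiseSd = "numeric", riseS = "numeric", decayS = "numeric",
                 photobleachCoeff = "numeric", illumination = "numeric",
                 responseAmplitude = "numeric", baselineWindowS = "numeric",
                 nCycles = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@frameRateHz <= 0) msg <- c(msg, "frameRateHz must be > 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@riseS <= 0 || object@decayS <= object@riseS)
      msg <- c(msg, "need 0 < riseS < decayS")
    if (object@nCycles < 1) msg <- c(msg, "nCycles must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname SimulationConfig-class
#' @param frameRateHz,pixelSizeUm,noiseSd,riseS,decayS see slots.
#' @param photobleachCoeff,illumination,responseAmplitude see slots.
#' @param baselineWindowS,nCycles,seed see slots.
#' @return A \code{SimulationConfig}.
#' @export
SimulationConfig <- function(frameRateHz = 10, pixelSizeUm = 12.9,
                             noiseSd = 0, riseS = 0.07, decayS = 0.54,
                             photobleachCoeff = 235, illumination = 89,
                             responseAmplitude = 0.05, baselineWindowS = 2,
                             nCycles = 2, seed = 1L) {
  new("SimulationConfig", frameRateHz = frameRateHz, pixelSizeUm = pixelSizeUm,
      noiseSd = noiseSd, riseS = riseS, decayS = decayS,
      photobleachCoeff = photobleachCoeff, illumination = illumination,
      responseAmplitude = responseAmplitude,
      baselineWindowS = baselineWindowS, nCycles = nCycles, seed = seed)
}

#' Fluorescence movie with stimulus timing
#'
#' Raw (non-negative) fluorescence organised as trials x time x rows x cols,
#' plus acquisition and stimulus metadata.  The stimulus onset is the time of
#' the first sweep start; the bar trajectory describes the periodic bar
#' motion from that onset.
#'
#' @slot data 4-D numeric array, trials x time x rows x cols.
#' @slot frameRate frames per second.
#' @slot direction stimulus direction label.
#' @slot onsetS stimulus onset time from movie start (s).
#' @slot trajectory a \linkS4class{BarTrajectory}.
#' @slot kind "raw" (non-negative fluorescence) or "deltaF" (baseline
#'   subtracted; may be negative).
#' @slot pixelSizeUm cortical pixel size (um).
#' @export
setClass("Movie",
  representation(data = "array", frameRate = "numeric",
                 direction = "character", onsetS = "numeric",
                 trajectory = "BarTrajectory", kind = "character",
                 pixelSizeUm = "numeric"),
  prototype(kind = "raw", pixelSizeUm = NA_real_),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 4)
      msg <- c(msg, "data must be a 4-D array (trials x time x rows x cols)")
    if (!object@kind %in% c("raw", "deltaF"))
      msg <- c(msg, "kind must be 'raw' or 'deltaF'")
    if (object@kind == "raw" && any(object@data < 0, na.rm = TRUE))
      msg <- c(msg, "raw fluorescence must be non-negative")
    if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
    if (object@onsetS < 0) msg <- c(msg, "onsetS must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "Movie", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "Movie (%s): %d trial(s) x %d frames x %d x %d px, %g Hz, direction %s, onset %.2f s\n",
    object@kind, d[1], d[2], d[3], d[4], object@frameRate, object@direction,
    object@onsetS))
})

#' @rdname Movie-class
#' @param x a \code{Movie}.
#' @export
setMethod("movieData", "Movie", function(x) x@data)

#' @rdname Movie-class
#' @export
setMethod("frameRate", "Movie", function(x) x@frameRate)

## ---------------------------------------------------------------------------
## Position / sign / patch maps
## ---------------------------------------------------------------------------

#' Retinotopic position maps
#'
#' Per-pixel preferred visual position (altitude and azimuth, degrees)
#' together with the first-harmonic response amplitude and a validity mask.
#' Pixels whose in-band amplitude falls below the validity floor carry NA
#' positions and valid = FALSE; the mask propagates to all downstream
#' analyses.
#'
#' @slot altitude,azimuth numeric matrices (degrees).
#' @slot amplitude numeric matrix (first-harmonic magnitude, delta F units).
#' @slot valid logical matrix.
#' @slot pixelSizeUm cortical pixel size (um); NA if unknown.
#' @export
setClass("PositionMaps",
  representation(altitude = "matrix", azimuth = "matrix",
                 amplitude = "matrix", valid = "matrix",
                 pixelSizeUm = "numeric"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@altitude)
    if (!identical(dim(object@azimuth), d) ||
        !identical(dim(object@amplitude), d) ||
        !identical(dim(object@valid), d))
      msg <- c(msg, "altitude, azimuth, amplitude and valid must share shape")
    v <- object@valid
    ## an axis may be wholly absent (all NA, e.g. a single-pair analysis);
    ## a present axis must be finite wherever the mask is valid
    for (ax in list(object@altitude, object@azimuth))
      if (any(is.finite(ax)) && any(!is.finite(ax[v])))
        msg <- c(msg, "positions must be finite where valid")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname PositionMaps-class
#' @param altitude,azimuth,amplitude,valid,pixelSizeUm see slots.
#' @return A \code{PositionMaps} object.
#' @export
PositionMaps <- function(altitude, azimuth, amplitude = NULL, valid = NULL,
                         pixelSizeUm = NA_real_) {
  if (is.null(amplitude))
    amplitude <- matrix(1, nrow(altitude), ncol(altitude))
  if (is.null(valid))
    valid <- is.finite(altitude) & is.finite(azimuth)
  new("PositionMaps", altitude = altitude, azimuth = azimuth,
      amplitude = amplitude, valid = valid, pixelSizeUm = pixelSizeUm)
}

setMethod("show", "PositionMaps", function(object) {
  cat(sprintf("PositionMaps: %d x %d px, %d valid (%.0f%%)\n",
              nrow(object@altitude), ncol(object@altitude),
              sum(object@valid), 100 * mean(object@valid)))
  if (any(object@valid))
    cat(sprintf("  altitude %.1f..%.1f deg, azimuth %.1f..%.1f deg\n",
                min(object@altitude[object@valid]),
                max(object@altitude[object@valid]),
                min(object@azimuth[object@valid]),
                max(object@azimuth[object@valid])))
})

#' @rdname PositionMaps-class
#' @param x a \code{PositionMaps}.
#' @export
setMethod("altitude", "PositionMaps", function(x) x@altitude)

#' @rdname PositionMaps-class
#' @export
setMethod("azimuth", "PositionMaps", function(x) x@azimuth)

#' @rdname PositionMaps-class
#' @export
setMethod("amplitudeMap", "PositionMaps", function(x) x@amplitude)

#' @rdname PositionMaps-class
#' @export
setMethod("validMask", "PositionMaps", function(x) x@valid)

#' Visual field sign map
#'
#' Per-pixel sine of the angle between the local azimuth and altitude
#' gradients, in [-1, 1]; NA/0 and valid = FALSE where the gradient is
#' undefined.
#'
#' @slot values numeric matrix in [-1, 1].
#' @slot valid logical matrix.
#' @slot pixelSizeUm cortical pixel size (um).
#' @export
setClass("SignMap",
  representation(values = "matrix", valid = "matrix", pixelSizeUm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@values), dim(object@valid)))
      msg <- c(msg, "values and valid must share shape")
    v <- object@values[object@valid]
    if (length(v) && any(abs(v) > 1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "|sign values| must be <= 1")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "SignMap", function(object) {
  cat(sprintf("SignMap: %d x %d px, %d valid, mean |S| %.2f\n",
              nrow(object@values), ncol(object@values), sum(object@valid),
              mean(abs(object@values[object@valid]))))
})

#' @rdname SignMap-class
#' @param x a \code{SignMap}.
#' @export
setMethod("fieldSign", "SignMap", function(x) x@values)

#' @rdname SignMap-class
#' @export
setMethod("validMask", "SignMap", function(x) x@valid)

#' Segmentation tunables for field-sign patch extraction
#'
#' The manually set variables of the border-identification routine.  The sign
#' map is Gaussian filtered (\code{signFilterSigmaUm}, interpreted in
#' cortical micrometers and converted by the pixel size; values smaller than
#' one pixel effectively skip the filter), thresholded at
#' \code{signThreshold}, cleaned by open/close operations
#' (\code{openCloseRadiusPx}), and suprathreshold patches are grown until
#' one-pixel (\code{borderWidthPx}) borders separate them.  Patches are then
#' split where internal visual-coverage redundancy exceeds
#' \code{redundancyThreshold} (watershed at eccentricity minima, prominence
#' \code{watershedProminenceDeg}) and same-sign neighbours below the
#' threshold are merged; patches under \code{minPatchPixels} are discarded.
#'
#' @slot signFilterSigmaUm Gaussian sigma for sign-map filtering (um).
#' @slot signThreshold absolute field-sign threshold in (0, 1).
#' @slot redundancyThreshold redundancy fraction (default 0.10).
#' @slot minPatchPixels minimum patch size (pixels).
#' @slot openCloseRadiusPx radius of the open/close structuring element (px).
#' @slot borderWidthPx inter-patch border width (px).
#' @slot coverageResolutionDeg visual-space grid resolution for redundancy (deg).
#' @slot watershedProminenceDeg minimum eccentricity prominence of watershed
#'   seeds (deg).
#' @slot maxIter maximum split/merge iterations.
#' @slot growthIter maximum label-growth iterations in binarisation.
#' @export
setClass("SegmentationParams",
  representation(signFilterSigmaUm = "numeric", signThreshold = "numeric",
                 redundancyThreshold = "numeric", minPatchPixels = "numeric",
                 openCloseRadiusPx = "numeric", borderWidthPx = "numeric",
                 coverageResolutionDeg = "numeric",
                 watershedProminenceDeg = "numeric", maxIter = "numeric",
                 growthIter = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@signThreshold <= 0 || object@signThreshold >= 1)
      msg <- c(msg, "signThreshold must lie in (0, 1)")
    if (object@minPatchPixels <= 0) msg <- c(msg, "minPatchPixels must be > 0")
    if (object@redundancyThreshold <= 0 || object@redundancyThreshold >= 1)
      msg <- c(msg, "redundancyThreshold must lie in (0, 1)")
    if (object@borderWidthPx < 1) msg <- c(msg, "borderWidthPx must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' @rdname SegmentationParams-class
#' @param signFilterSigmaUm,signThreshold,redundancyThreshold see slots.
#' @param minPatchPixels,openCloseRadiusPx,borderWidthPx see slots.
#' @param coverageResolutionDeg,watershedProminenceDeg,maxIter,growthIter see slots.
#' @return A \code{SegmentationParams}.
#' @export
SegmentationParams <- function(signFilterSigmaUm = 8.14, signThreshold = 0.32,
                               redundancyThreshold = 0.10,
                               minPatchPixels = 100, openCloseRadiusPx = 1,
                               borderWidthPx = 1, coverageResolutionDeg = 1,
                               watershedProminenceDeg = 1, maxIter = 10,
                               growthIter = 40) {
  new("SegmentationParams", signFilterSigmaUm = signFilterSigmaUm,
      signThreshold = signThreshold,
      redundancyThreshold = redundancyThreshold,
      minPatchPixels = minPatchPixels, openCloseRadiusPx = openCloseRadiusPx,
      borderWidthPx = borderWidthPx,
      coverageResolutionDeg = coverageResolutionDeg,
      watershedProminenceDeg = watershedProminenceDeg, maxIter = maxIter,
      growthIter = growthIter)
}

#' Labeled retinotopic patches with borders
#'
#' Result of segmenting a sign map: an integer label image (0 = background or
#' border), a patch table (id, sign, pixel count, optional area name), the
#' raw -1/0/+1 image the labels came from, and border pixels.
#'
#' @slot labels integer matrix of patch ids (0 background/border).
#' @slot patches data.frame: id, sign, nPixels, name.
#' @slot raw numeric matrix with values -1/0/+1 (thresholded sign map).
#' @slot borders two-column matrix (row, col) of border pixels lying between
#'   adjacent patches.
#' @slot pixelSizeUm cortical pixel size (um).
#' @export
setClass("PatchMap",
  representation(labels = "matrix", patches = "data.frame", raw = "matrix",
                 borders = "matrix", pixelSizeUm = "numeric"),
  validity = function(object) {
    msg <- NULL
    ids <- setdiff(unique(as.vector(object@labels)), 0L)
    if (!all(ids %in% object@patches$id))
      msg <- c(msg, "label image contains ids missing from the patch table")
    if (nrow(object@patches) &&
        !all(object@patches$sign %in% c(-1L, 1L)))
      msg <- c(msg, "patch signs must be -1 or +1")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "PatchMap", function(object) {
  cat(sprintf("PatchMap: %d x %d px, %d patch(es)\n",
              nrow(object@labels), ncol(object@labels),
              nrow(object@patches)))
  if (nrow(object@patches)) {
    p <- object@patches
    for (i in seq_len(nrow(p)))
      cat(sprintf("  #%d %-6s sign %+d  %5d px\n", p$id[i],
                  ifelse(is.na(p$name[i]), "", p$name[i]), p$sign[i],
                  p$nPixels[i]))
  }
})

#' @rdname PatchMap-class
#' @param x a \code{PatchMap}.
#' @export
setMethod("labelImage", "PatchMap", function(x) x@labels)

#' @rdname PatchMap-class
#' @export
setMethod("patchTable", "PatchMap", function(x) x@patches)

## ---------------------------------------------------------------------------
## Coverage
## ---------------------------------------------------------------------------

#' Binary occupancy of a visual-space grid
#'
#' Rows of the grid run over altitude (increasing with row index), columns
#' over azimuth.  The covered area is the number of occupied cells times the
#' squared resolution.
#'
#' @slot grid logical matrix (altitude x azimuth cells).
#' @slot resolutionDeg cell size (degrees).
#' @slot extentDeg numeric length-4: azimuth min/max, altitude min/max of the
#'   grid (cell edges).
#' @export
setClass("CoverageMask",
  representation(grid = "matrix", resolutionDeg = "numeric",
                 extentDeg = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@resolutionDeg <= 0) msg <- c(msg, "resolutionDeg must be > 0")
    if (length(object@extentDeg) != 4)
      msg <- c(msg, "extentDeg must be c(aziMin, aziMax, altMin, altMax)")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "CoverageMask", function(object) {
  cat(sprintf("CoverageMask: %d x %d cells @ %g deg, area %.0f deg^2\n",
              nrow(object@grid), ncol(object@grid), object@resolutionDeg,
              coverageArea(object)))
})

#' @rdname CoverageMask-class
#' @param x a \code{CoverageMask}.
#' @export
setMethod("coverageArea", "CoverageMask",
          function(x) sum(x@grid) * x@resolutionDeg^2)

#' @rdname CoverageMask-class
#' @export
setMethod("gridResolution", "CoverageMask", function(x) x@resolutionDeg)

## ---------------------------------------------------------------------------
## Pupil
## ---------------------------------------------------------------------------

#' Per-frame pupil detection result
#'
#' @slot centroidPx pupil centroid c(x, y) in pixels (NA when blink/lost).
#' @slot glintPx LED glint centroid c(x, y) in pixels.
#' @slot areaMm2 pupil area (mm^2).
#' @slot blink TRUE when the glint is absent (eyelid closed).
#' @slot lost TRUE when the glint is present but no pupil candidate survived.
#' @slot outline two-column matrix (row, col) of pupil pixels.
#' @export
setClass("PupilState",
  representation(centroidPx = "numeric", glintPx = "numeric",
                 areaMm2 = "numeric", blink = "logical", lost = "logical",
                 outline = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (!is.na(object@areaMm2) && object@areaMm2 < 0)
      msg <- c(msg, "areaMm2 must be >= 0")
    if (isTRUE(object@blink) && nrow(object@outline) > 0)
      msg <- c(msg, "a blink frame cannot carry a pupil outline")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "PupilState", function(object) {
  if (object@blink) cat("PupilState: blink\n")
  else if (object@lost) cat("PupilState: lost (glint present, no pupil)\n")
  else cat(sprintf("PupilState: centroid (%.1f, %.1f) px, area %.4f mm^2\n",
                   object@centroidPx[1], object@centroidPx[2],
                   object@areaMm2))
})

## ---------------------------------------------------------------------------
## Receptive fields
## ---------------------------------------------------------------------------

#' On/Off receptive-field maps for one cell
#'
#' Raw maps hold the mean 0-300 ms delta F/F integral per stimulus location;
#' z maps are z-scored over map pixels (population SD), then smoothed and
#' up-sampled.  A cell is responsive when the maximum of the smoothed On or
#' Off z map exceeds 2.
#'
#' @slot on,off raw maps over the stimulus grid (delta F/F x s).
#' @slot zOn,zOff smoothed, up-sampled z-score maps.
#' @slot gridAltDeg,gridAziDeg cell-center coordinates of the raw grid (deg).
#' @slot upAltDeg,upAziDeg coordinates of the up-sampled grid (deg).
#' @slot responsive logical flag.
#' @export
setClass("RfMaps",
  representation(on = "matrix", off = "matrix", zOn = "matrix",
                 zOff = "matrix", gridAltDeg = "numeric",
                 gridAziDeg = "numeric", upAltDeg = "numeric",
                 upAziDeg = "numeric", responsive = "logical"),
  validity = function(object) {
    if (!identical(dim(object@on), dim(object@off)))
      "On and Off maps must share shape" else TRUE
  })

setMethod("show", "RfMaps", function(object) {
  cat(sprintf("RfMaps: %d x %d stimulus grid, max z %.2f, responsive: %s\n",
              nrow(object@on), ncol(object@on),
              max(object@zOn, object@zOff), object@responsive))
})

## ---------------------------------------------------------------------------
## Projection retinotopy
## ---------------------------------------------------------------------------

#' Weighted source center-of-mass field from tracer experiments
#'
#' Per target voxel, the estimated 3-D source location (center of mass of all
#' injection centers, weighted by normalized projection strength
#' W = Ft / Fs) and the summed weight.  L is defined only where the weight
#' sum is positive.
#'
#' @slot L 4-D array (x, y, z, 3): source-location components.
#' @slot weightSum 3-D array of summed weights.
#' @export
setClass("ProjectionField",
  representation(L = "array", weightSum = "array"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@L)) != 4 || dim(object@L)[4] != 3)
      msg <- c(msg, "L must be x * y * z * 3")
    if (!identical(dim(object@L)[1:3], dim(object@weightSum)))
      msg <- c(msg, "L and weightSum must share the voxel grid")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "ProjectionField", function(object) {
  d <- dim(object@weightSum)
  cat(sprintf("ProjectionField: %d x %d x %d voxels, %d connected\n",
              d[1], d[2], d[3], sum(object@weightSum > 0)))
})

#' Normalized cortical depth field
#'
#' Solution of the Laplace equation between the pia (0) and white matter (1)
#' boundaries; interior values lie strictly inside (0, 1).
#'
#' @slot depth 3-D numeric array (NA outside cortex).
#' @slot cortexMask logical 3-D array.
#' @export
setClass("DepthField",
  representation(depth = "array", cortexMask = "array"),
  validity = function(object) {
    v <- object@depth[object@cortexMask]
    if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
      "depth values must lie in [0, 1]" else TRUE
  })

setMethod("show", "DepthField", function(object) {
  d <- dim(object@depth)
  cat(sprintf("DepthField: %d x %d x %d voxels, %d in cortex\n",
              d[1], d[2], d[3], sum(object@cortexMask)))
})
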
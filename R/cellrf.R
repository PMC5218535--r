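#' @include AllClasses.R utils.R stimulus.R
NULL

## Calcium response to an impulse train: difference-of-exponentials kernel
## (finite rise, slower decay), realized as two recursive filters and
## normalized to unit peak response.
impulseResponse <- function(weights, decayS, frameRate, riseS = 0.07) {
  ad <- exp(-1 / (decayS * frameRate))
  ar <- exp(-1 / (riseS * frameRate))
  x <- as.numeric(stats::filter(weights, ad, method = "recursive")) -
    as.numeric(stats::filter(weights, ar, method = "recursive"))
  tt <- seq(0, 5 * decayS, by = 1 / frameRate)
  peak <- max(exp(-tt / decayS) - exp(-tt / riseS))
  x / peak
}

#' Simulate a two-photon sparse-noise session
#'
#' Generates somatic traces with known Gaussian receptive fields, tuned
#' neuropil traces, and measured traces contaminated as
#' \code{measured = true + r * neuropil} with a known per-cell ratio r.
#' Each soma's neuropil trace is tuned close to the soma's own receptive
#' field (jittered by \code{neuropilTuningJitterDeg}), as local neuropil
#' shares the retinotopy of its parent population; it also carries a slow
#' ongoing component and a fast frame-to-frame fluctuation shared with the
#' soma only through the contamination.  In the default mirrored layout,
#' somata straddle a retinotopic border at x = 0 um: the azimuth of the
#' preferred position rises with distance from the border on both sides,
#' with a steeper slope on the LM side (smaller cortical magnification
#' than V1).
#'
#' @param nCells number of somata.
#' @param spec a \linkS4class{SparseNoiseSpec} (default 6-degree squares on
#'   an 11 x 13 grid, 60 repeats per polarity).
#' @param rTrue contamination ratio(s), recycled over cells (default 0.244).
#' @param frameRate imaging rate (Hz).
#' @param noiseSd additive noise SD on each trace (delta F units).
#' @param neuropilAmplitude response amplitude of the tuned neuropil
#'   component relative to a somatic response; must be positive for r to
#'   be identifiable, and the generator enforces this.
#' @param neuropilFastSd SD of the fast (frame-to-frame) neuropil
#'   fluctuation.  Neuropil pools many processes and fluctuates faster
#'   than any one soma; this component enters the somatic trace through
#'   the contamination and is what makes the ratio r identifiable by the
#'   smoothness objective.
#' @param neuropilTuningJitterDeg SD of the offset between a soma's tuning
#'   and its neuropil's tuning (degrees).
#' @param layout "mirrored" (V1/LM border geometry) or "random".
#' @param magV1,magLM cortical magnification on each side (deg/um).
#' @param seed integer seed.
#' @return A list: \code{cells} (data.frame: id, rfAltDeg, rfAziDeg,
#'   npAltDeg, npAziDeg, somaXUm, somaYUm, side, rTrue), \code{events},
#'   \code{true}, \code{measured}, \code{neuropil} (nFrames x nCells
#'   matrices), \code{frameRate}, \code{spec}.
#' @export
simulateTwoPhotonSession <- function(nCells = 20, spec = SparseNoiseSpec(),
                                     rTrue = 0.244, frameRate = 30,
                                     noiseSd = 0.01,
                                     neuropilAmplitude = 0.6,
                                     neuropilFastSd = 0.15,
                                     neuropilTuningJitterDeg = 2,
                                     layout = c("mirrored", "random"),
                                     magV1 = 0.05, magLM = 0.1, seed = 1L) {
  layout <- match.arg(layout)
  stopIfNot(all(rTrue >= 0), "rTrue must be >= 0")
  stopIfNot(neuropilAmplitude > 0,
            "neuropil amplitude must be positive, or r is unidentifiable")
  events <- sparseNoiseEvents(spec, seed)
  nFrames <- ceiling((max(events$onsetS) + spec@durationS + 2) * frameRate)
  e <- spec@gridExtentDeg
  rTrue <- rep_len(rTrue, nCells)
  cells <- withLocalSeed(seed + 1, {
    if (layout == "mirrored") {
      x <- stats::runif(nCells, -200, 200)
      y <- stats::runif(nCells, -200, 200)
      side <- ifelse(x < 0, "LM", "V1")
      mag <- ifelse(side == "V1", magV1, magLM)
      azi <- mean(e[1:2]) - 10 + abs(x) * mag
      alt <- mean(e[3:4]) + y * 0.04
      data.frame(id = seq_len(nCells), rfAltDeg = alt, rfAziDeg = azi,
                 somaXUm = x, somaYUm = y, side = side, rTrue = rTrue)
    } else {
      data.frame(id = seq_len(nCells),
                 rfAltDeg = stats::runif(nCells, e[3] + 12, e[4] - 12),
                 rfAziDeg = stats::runif(nCells, e[1] + 12, e[2] - 12),
                 somaXUm = stats::runif(nCells, -200, 200),
                 somaYUm = stats::runif(nCells, -200, 200),
                 side = "V1", rTrue = rTrue)
    }
  })
  sigma <- spec@squareSizeDeg
  onsetFrames <- round(events$onsetS * frameRate) + 1
  makeTrace <- function(altC, aziC, onAmp, offAmp) {
    w <- exp(-((events$altitudeDeg - altC)^2 +
                 (events$azimuthDeg - aziC)^2) / (2 * sigma^2)) *
      ifelse(events$polarity > 0, onAmp, offAmp)
    imp <- numeric(nFrames)
    imp[onsetFrames] <- imp[onsetFrames] + w
    impulseResponse(imp, decayS = 0.4, frameRate = frameRate)
  }
  tSec <- (seq_len(nFrames) - 1) / frameRate
  slow <- 0.05 * sin(2 * pi * tSec / 37)   # shared ongoing component
  cells$npAltDeg <- cells$rfAltDeg +
    withLocalSeed(seed + 3, stats::rnorm(nCells, sd = neuropilTuningJitterDeg))
  cells$npAziDeg <- cells$rfAziDeg +
    withLocalSeed(seed + 4, stats::rnorm(nCells, sd = neuropilTuningJitterDeg))
  true <- matrix(0, nFrames, nCells)
  measured <- matrix(0, nFrames, nCells)
  neuropil <- matrix(0, nFrames, nCells)
  withLocalSeed(seed + 2, {
    for (i in seq_len(nCells)) {
      np <- neuropilAmplitude *
        makeTrace(cells$npAltDeg[i], cells$npAziDeg[i], 1, 0.7) +
        slow + stats::rnorm(nFrames, sd = neuropilFastSd)
      tr <- 1 + makeTrace(cells$rfAltDeg[i], cells$rfAziDeg[i], 1, 0.7)
      if (noiseSd > 0) tr <- tr + stats::rnorm(nFrames, sd = noiseSd)
      neuropil[, i] <- np
      true[, i] <- tr
      measured[, i] <- tr + cells$rTrue[i] * np
    }
  })
  list(cells = cells, events = events, true = true, measured = measured,
       neuropil = neuropil, frameRate = frameRate, spec = spec)
}

#' Build neuropil annulus masks around somatic ROIs
#'
#' Each neuropil region is the band between dilations of the soma's outer
#' border by the inner and outer radii (5 and 15 px), with the union of all
#' somatic ROIs excluded.  Somata outside the size window (59-395.5 um^2)
#' are removed before annulus construction; somata whose annulus is empty
#' after exclusion are flagged.
#'
#' @param somaMasks list of logical matrices (one per soma, common frame).
#' @param innerPx,outerPx dilation radii bounding the annulus (pixels).
#' @param pixelSizeUm pixel size (um; default 1.4).
#' @param sizeRangeUm2 numeric pair: soma area window (um^2).
#' @return A list: \code{somas} (kept masks), \code{neuropil} (annulus
#'   masks), \code{keptIds} (indices into the input), \code{emptyAnnulus}
#'   (logical per kept soma).
#' @export
buildNeuropilMasks <- function(somaMasks, innerPx = 5, outerPx = 15,
                               pixelSizeUm = 1.4,
                               sizeRangeUm2 = c(59, 395.5)) {
  areas <- vapply(somaMasks, sum, numeric(1)) * pixelSizeUm^2
  keep <- which(areas >= sizeRangeUm2[1] & areas <= sizeRangeUm2[2])
  stopIfNot(length(keep) > 0, "no soma passes the size filter")
  somas <- somaMasks[keep]
  somaUnion <- Reduce("|", somaMasks)
  neuropil <- lapply(somas, function(m)
    dilateMask(m, outerPx) & !dilateMask(m, innerPx) & !somaUnion)
  list(somas = somas, neuropil = neuropil, keptIds = keep,
       emptyAnnulus = !vapply(neuropil, any, logical(1)))
}

#' Estimate and subtract neuropil contamination
#'
#' The contamination ratio r is the value that makes the corrected trace
#' \code{Fc = Fmeasured - r * Fneuropil} smoothest, measured by the
#' second-difference (roughness) norm; because the objective is quadratic
#' in r the minimizer has the closed form of a regression of the measured
#' trace's curvature on the neuropil trace's curvature, clipped to
#' [0, rMax].
#'
#' @param fMeasured,fNeuropil numeric traces of equal length.
#' @param rMax upper clip for r (default 20, accommodating deliberately
#'   exaggerated contamination in robustness tests).
#' @return A list: \code{r} and \code{corrected} (the subtracted trace).
#' @export
estimateNeuropilRatio <- function(fMeasured, fNeuropil, rMax = 20) {
  stopIfNot(length(fMeasured) == length(fNeuropil),
            "traces must have equal length")
  d2m <- diff(fMeasured, differences = 2)
  d2n <- diff(fNeuropil, differences = 2)
  den <- sum(d2n^2)
  if (den < 1e-12 * length(d2n)) {
    warning("neuropil trace is degenerate (no variance); r set to 0")
    r <- 0
  } else {
    r <- sum(d2m * d2n) / den
    r <- min(max(r, 0), rMax)
  }
  list(r = r, corrected = fMeasured - r * fNeuropil)
}

#' Compute On/Off receptive-field maps from a corrected trace
#'
#' For each stimulus location and polarity, the mean over repeats of the
#' delta F/F integral in the 300 ms after onset (baseline: mean fluorescence
#' in the 0.5 s before onset) gives the raw On (white) and Off (black)
#' maps.  Each map is z-scored over its pixels (population SD), smoothed
#' with a Gaussian of sigma 6 degrees and up-sampled tenfold with cubic
#' interpolation.  The cell is responsive when the maximum of the smoothed
#' On or Off z map exceeds 2.
#'
#' @param trace corrected fluorescence trace.
#' @param events event table from \code{\link{sparseNoiseEvents}}.
#' @param frameRate imaging rate (Hz).
#' @param baselineS baseline window before onset (s).
#' @param windowS integration window after onset (s).
#' @param smoothSigmaDeg z-map smoothing sigma (degrees).
#' @param upsampleFactor up-sampling factor.
#' @param zThreshold responsiveness threshold on the z maps.
#' @return An \linkS4class{RfMaps}.
#' @export
computeRfMaps <- function(trace, events, frameRate, baselineS = 0.5,
                          windowS = 0.3, smoothSigmaDeg = 6,
                          upsampleFactor = 10, zThreshold = 2) {
  altC <- sort(unique(events$altitudeDeg))
  aziC <- sort(unique(events$azimuthDeg))
  cellDeg <- if (length(altC) > 1) altC[2] - altC[1] else smoothSigmaDeg
  nBase <- max(1, round(baselineS * frameRate))
  nWin <- max(1, round(windowS * frameRate))
  onset <- round(events$onsetS * frameRate) + 1
  ok <- onset - nBase >= 1 & onset + nWin - 1 <= length(trace)
  ev <- events[ok, ]; onset <- onset[ok]
  baseIdx <- outer(onset, -(nBase:1), "+")
  base <- matrix(trace[baseIdx], nrow(ev), nBase)
  f0 <- rowMeans(base)
  winIdx <- outer(onset, 0:(nWin - 1), "+")
  resp <- matrix(trace[winIdx], nrow(ev), nWin)
  integ <- rowSums((resp - f0) / f0) / frameRate
  mapOf <- function(pol) {
    m <- matrix(0, length(altC), length(aziC))
    sel <- ev$polarity == pol
    agg <- tapply(integ[sel], list(ev$row[sel], ev$col[sel]), mean)
    m[cbind(as.integer(rep(rownames(agg), ncol(agg))),
            as.integer(rep(colnames(agg), each = nrow(agg))))] <-
      as.vector(agg)
    m
  }
  on <- mapOf(1L); off <- mapOf(-1L)
  zScore <- function(m) (m - mean(m)) / sqrt(mean((m - mean(m))^2))
  zsm <- function(m) gaussianBlur(zScore(m), smoothSigmaDeg / cellDeg)
  zOnS <- zsm(on); zOffS <- zsm(off)
  responsive <- max(zOnS, zOffS) > zThreshold
  zOn <- splineUpsample(zOnS, upsampleFactor)
  zOff <- splineUpsample(zOffS, upsampleFactor)
  upAlt <- altC[1] + ((seq_len(length(altC) * upsampleFactor) - 0.5) /
                        upsampleFactor - 0.5) * cellDeg
  upAzi <- aziC[1] + ((seq_len(length(aziC) * upsampleFactor) - 0.5) /
                        upsampleFactor - 0.5) * cellDeg
  new("RfMaps", on = on, off = off, zOn = zOn, zOff = zOff,
      gridAltDeg = altC, gridAziDeg = aziC, upAltDeg = upAlt,
      upAziDeg = upAzi, responsive = responsive)
}

#' Receptive-field center from thresholded On/Off maps
#'
#' Pixels of each z map below 40 percent of the larger of the On and Off
#' maxima are zeroed; the thresholded maps are summed and the center is the
#' weighted average coordinate of the combined field.
#'
#' @param rf an \linkS4class{RfMaps} (must be responsive).
#' @param thresholdFrac threshold as a fraction of the larger maximum.
#' @return Named numeric: \code{altitude}, \code{azimuth} (degrees).
#' @export
rfCenter <- function(rf, thresholdFrac = 0.4) {
  stopIfNot(rf@responsive, "receptive field is not responsive")
  thr <- thresholdFrac * max(max(rf@zOn), max(rf@zOff))
  zo <- rf@zOn; zf <- rf@zOff
  zo[zo < thr] <- 0; zf[zf < thr] <- 0
  comb <- zo + zf
  stopIfNot(any(comb > 0), "all pixels fall below the threshold")
  ctr <- weightedCentroid(comb, rf@upAltDeg, rf@upAziDeg)
  c(altitude = ctr[1], azimuth = ctr[2])
}

## Minimum distance from points to a polyline, signed by the side of the
## nearest segment (positive to the left of the segment direction).
signedPolylineDistance <- function(px, py, border) {
  nSeg <- nrow(border) - 1
  stopIfNot(nSeg >= 1, "border polyline needs at least two points")
  best <- rep(Inf, length(px)); sgn <- rep(1, length(px))
  for (s in seq_len(nSeg)) {
    a <- border[s, ]; b <- border[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- pmax(0, pmin(1, ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2))
    qx <- a[1] + t * ab[1]; qy <- a[2] + t * ab[2]
    d <- sqrt((px - qx)^2 + (py - qy)^2)
    cross <- ab[1] * (py - a[2]) - ab[2] * (px - a[1])
    upd <- d < best
    best[upd] <- d[upd]
    sgn[upd] <- ifelse(cross[upd] >= 0, 1, -1)
  }
  best * sgn
}

#' Receptive-field position as a function of distance to a border
#'
#' Computes the signed shortest Cartesian distance from each soma to the
#' border polyline (positive on the left of the polyline direction) and
#' bins the receptive-field altitude and azimuth by that distance.
#'
#' @param somaXUm,somaYUm soma centroid coordinates (um).
#' @param rfAltDeg,rfAziDeg receptive-field centers (degrees).
#' @param border two-column matrix of polyline vertices (um).
#' @param binUm bin width (um; default 20).
#' @return A list: \code{distanceUm} (signed, per soma) and \code{profile}
#'   (data.frame: binCenterUm, n, meanAlt, sdAlt, meanAzi, sdAzi).
#' @export
borderDistanceProfile <- function(somaXUm, somaYUm, rfAltDeg, rfAziDeg,
                                  border, binUm = 20) {
  d <- signedPolylineDistance(somaXUm, somaYUm, border)
  bin <- floor(d / binUm)
  agg <- function(v, f) vapply(split(v, bin), f, numeric(1))
  prof <- data.frame(
    binCenterUm = (as.numeric(names(split(d, bin))) + 0.5) * binUm,
    n = as.numeric(table(bin)),
    meanAlt = agg(rfAltDeg, mean), sdAlt = agg(rfAltDeg, stats::sd),
    meanAzi = agg(rfAziDeg, mean), sdAzi = agg(rfAziDeg, stats::sd),
    row.names = NULL)
  list(distanceUm = d, profile = prof[order(prof$binCenterUm), ])
}
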
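#' @include AllClasses.R utils.R fieldsign.R
NULL

## Principal axis (degrees, in (-90, 90]) of the azimuth gradient over a
## mask: leading eigenvector of the gradient second-moment matrix.
azimuthGradientAxis <- function(maps, mask) {
  g <- maskedGradient(azimuth(maps))
  idx <- which(mask & validMask(maps))
  gx <- g$dcol[idx]; gy <- g$drow[idx]
  ok <- is.finite(gx) & is.finite(gy)
  M <- matrix(c(sum(gx[ok]^2), sum(gx[ok] * gy[ok]),
                sum(gx[ok] * gy[ok]), sum(gy[ok]^2)), 2, 2)
  v <- eigen(M, symmetric = TRUE)$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  ang
}

#' Align a map to the common reference frame
#'
#' Translates the maps so the V1 centroid sits at the frame center, rotates
#' so the principal axis of the azimuth gradient over V1 matches the
#' reference axis, and (optionally) subtracts altitude/azimuth offsets so a
#' chosen landmark — conventionally the V1/LM/RL border point — reads
#' (0, 0) degrees, correcting mouse-to-monitor positioning differences.
#'
#' @param maps a \linkS4class{PositionMaps}.
#' @param pm a \linkS4class{PatchMap} in which V1 is identifiable.
#' @param v1 patch name or id of V1.
#' @param borderPoint optional c(row, col) of the landmark whose visual
#'   position is subtracted; NULL skips the offset correction.
#' @param referenceAngleDeg target axis angle (degrees; default 0 = columns).
#' @return A list: \code{maps} (aligned \linkS4class{PositionMaps}),
#'   \code{transform} (translation px, rotation deg, altitude/azimuth
#'   offsets deg).
#' @export
alignMap <- function(maps, pm, v1 = "V1", borderPoint = NULL,
                     referenceAngleDeg = 0) {
  mask <- tryCatch(patchMask(pm, v1), error = function(e)
    stop("V1 patch not found: ", conditionMessage(e)))
  stopIfNot(any(mask), "V1 patch is empty")
  ctr <- maskCentroid(mask)
  nr <- nrow(maps@altitude); nc <- ncol(maps@altitude)
  frameCtr <- c((nr + 1) / 2, (nc + 1) / 2)
  ang <- azimuthGradientAxis(maps, mask)
  rot <- referenceAngleDeg - ang
  th <- rot * pi / 180
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  dr <- g$row - frameCtr[1]; dc <- g$col - frameCtr[2]
  ## inverse map: rotate output offsets by -rot, then shift to V1 centroid
  srcR <- ctr[1] + cos(th) * dr - sin(th) * dc
  srcC <- ctr[2] + sin(th) * dr + cos(th) * dc
  sampleTo <- function(m) matrix(bilinearSample(m, srcR, srcC), nr, nc)
  altOff <- 0; aziOff <- 0
  if (!is.null(borderPoint)) {
    altOff <- maps@altitude[borderPoint[1], borderPoint[2]]
    aziOff <- maps@azimuth[borderPoint[1], borderPoint[2]]
    stopIfNot(is.finite(altOff) && is.finite(aziOff),
              "border point has no valid position")
  }
  alt <- sampleTo(maps@altitude) - altOff
  azi <- sampleTo(maps@azimuth) - aziOff
  amp <- sampleTo(maps@amplitude)
  vv <- matrix(bilinearSample((maps@valid) * 1, srcR, srcC, fill = 0),
               nr, nc) > 0.999
  vv <- vv & is.finite(alt) & is.finite(azi)
  alt[!vv] <- NA_real_; azi[!vv] <- NA_real_; amp[!vv] <- 0
  list(maps = PositionMaps(alt, azi, amp, vv, maps@pixelSizeUm),
       transform = list(translationPx = frameCtr - ctr, rotationDeg = rot,
                        altitudeOffsetDeg = altOff,
                        azimuthOffsetDeg = aziOff))
}

## Phasor encoding of positions over a linear extent.
posToPhasor <- function(pos, lo, hi)
  exp(2i * pi * (pos - lo) / (hi - lo))
phasorToPos <- function(z, lo, hi)
  lo + (hi - lo) * ((Arg(z) / (2 * pi)) %% 1)

#' Mean maps across animals by vector summation
#'
#' Positions are converted to unit phasors over the given extents, averaged
#' pixel-by-pixel across maps (ignoring invalid pixels), and converted back;
#' the mean field sign map is the arithmetic per-pixel mean of the
#' individual sign maps.  Borders are regenerated from the mean sign map
#' (threshold 0.3) with the standard split/merge processing.
#'
#' @param mapsList list of aligned \linkS4class{PositionMaps} on one frame.
#' @param altitudeExtent,azimuthExtent numeric pairs: the position range
#'   mapped to one phasor revolution; defaults to the pooled data range.
#' @param params \linkS4class{SegmentationParams} for the border
#'   regeneration; the sign threshold defaults to 0.3 here.
#' @param segment logical; skip border regeneration when FALSE.
#' @return A list: \code{maps} (mean \linkS4class{PositionMaps}),
#'   \code{sign} (mean \linkS4class{SignMap}), \code{consistency} (mean
#'   resultant length per pixel, azimuth/altitude averaged), and
#'   \code{patches} (a \linkS4class{PatchMap}, or NULL).
#' @export
meanMaps <- function(mapsList, altitudeExtent = NULL, azimuthExtent = NULL,
                     params = SegmentationParams(signThreshold = 0.3),
                     segment = TRUE) {
  stopIfNot(length(mapsList) >= 1, "need at least one map")
  d <- dim(mapsList[[1]]@altitude)
  for (m in mapsList)
    stopIfNot(identical(dim(m@altitude), d), "maps must share one frame")
  rng <- function(get) range(unlist(lapply(mapsList, function(m)
    get(m)[validMask(m)])), finite = TRUE)
  if (is.null(altitudeExtent)) {
    altitudeExtent <- rng(altitude); altitudeExtent[2] <-
      altitudeExtent[2] + diff(altitudeExtent) * 0.02 + 1e-6
  }
  if (is.null(azimuthExtent)) {
    azimuthExtent <- rng(azimuth); azimuthExtent[2] <-
      azimuthExtent[2] + diff(azimuthExtent) * 0.02 + 1e-6
  }
  zAlt <- matrix(0 + 0i, d[1], d[2]); zAzi <- zAlt
  nValid <- matrix(0, d[1], d[2])
  sSum <- matrix(0, d[1], d[2]); sN <- matrix(0, d[1], d[2])
  for (m in mapsList) {
    v <- validMask(m)
    za <- posToPhasor(m@altitude, altitudeExtent[1], altitudeExtent[2])
    zz <- posToPhasor(m@azimuth, azimuthExtent[1], azimuthExtent[2])
    za[!v] <- 0; zz[!v] <- 0
    zAlt <- zAlt + za; zAzi <- zAzi + zz
    nValid <- nValid + v
    sm <- computeSignMap(m)
    sv <- sm@values; ok <- sm@valid
    sSum[ok] <- sSum[ok] + sv[ok]; sN <- sN + ok
  }
  valid <- nValid > 0
  zAlt[valid] <- zAlt[valid] / nValid[valid]
  zAzi[valid] <- zAzi[valid] / nValid[valid]
  alt <- phasorToPos(zAlt, altitudeExtent[1], altitudeExtent[2])
  azi <- phasorToPos(zAzi, azimuthExtent[1], azimuthExtent[2])
  alt[!valid] <- NA_real_; azi[!valid] <- NA_real_
  consistency <- (Mod(zAlt) + Mod(zAzi)) / 2
  meanPos <- PositionMaps(alt, azi, consistency, valid,
                          mapsList[[1]]@pixelSizeUm)
  sMean <- matrix(NA_real_, d[1], d[2])
  sOk <- sN > 0
  sMean[sOk] <- sSum[sOk] / sN[sOk]
  signMap <- new("SignMap", values = sMean, valid = sOk,
                 pixelSizeUm = mapsList[[1]]@pixelSizeUm)
  patches <- NULL
  if (segment) {
    raw <- binarizeSignMap(signMap, params)
    patches <- if (nrow(raw@patches))
      splitMergePatches(raw, meanPos, params) else raw
  }
  list(maps = meanPos, sign = signMap, consistency = consistency,
       patches = patches)
}

#' Across-animal variance map of the field sign
#'
#' @param signList list of \linkS4class{SignMap}s on one frame (>= 2).
#' @return A numeric matrix: per-pixel population variance (denominator n)
#'   of the sign values across maps, NA where fewer than two maps are valid.
#' @export
varianceMap <- function(signList) {
  stopIfNot(length(signList) >= 2, "variance needs at least two maps")
  d <- dim(signList[[1]]@values)
  s <- matrix(0, d[1], d[2]); s2 <- matrix(0, d[1], d[2])
  n <- matrix(0, d[1], d[2])
  for (m in signList) {
    v <- m@valid & is.finite(m@values)
    s[v] <- s[v] + m@values[v]
    s2[v] <- s2[v] + m@values[v]^2
    n <- n + v
  }
  out <- matrix(NA_real_, d[1], d[2])
  ok <- n >= 2
  out[ok] <- s2[ok] / n[ok] - (s[ok] / n[ok])^2
  pmax(out, 0)
}

#' Incidence of named patches across a cohort
#'
#' For each area name, the number of maps containing it over the number of
#' maps whose cranial window contains the area's expected location; areas
#' outside every window are reported as not assessable (NA incidence).
#'
#' @param patchMaps list of \linkS4class{PatchMap}s with named patches.
#' @param windows list of logical matrices (imaged window per animal).
#' @param expectedLoc named list of c(row, col) expected locations.
#' @return A data.frame: name, nPresent, nAssessable, incidence.
#' @export
patchIncidence <- function(patchMaps, windows, expectedLoc) {
  stopIfNot(length(patchMaps) == length(windows),
            "one window mask per patch map is required")
  out <- NULL
  for (nm in names(expectedLoc)) {
    loc <- expectedLoc[[nm]]
    assessable <- vapply(windows, function(w) isTRUE(w[loc[1], loc[2]]),
                         logical(1))
    present <- vapply(seq_along(patchMaps), function(i)
      assessable[i] && nm %in% patchMaps[[i]]@patches$name, logical(1))
    nA <- sum(assessable)
    out <- rbind(out, data.frame(
      name = nm, nPresent = sum(present), nAssessable = nA,
      incidence = if (nA > 0) sum(present) / nA else NA_real_))
  }
  out
}

#' k-means style cluster-consistency metric for patch locations
#'
#' For each patch name, the dispersion of its centroids across maps (mean
#' distance to the group centroid) is normalized by the expected dispersion
#' of an equally sized group drawn from the pooled centroids with labels
#' shuffled.  C_k near 0 marks a tightly clustered, consistently placed
#' patch; C_k near 1 is indistinguishable from the shuffled null.  A patch
#' is significant when its observed dispersion falls below the alpha
#' quantile of its null distribution.
#'
#' @param centroids data.frame with columns \code{map}, \code{name},
#'   \code{x}, \code{y} (one row per patch occurrence).
#' @param nShuffles number of label shuffles for the null (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed for the shuffles.
#' @param minMaps minimum occurrences for a patch to be assessed.
#' @return A data.frame: name, n, Ck, pValue, significant (NA row when a
#'   patch has fewer than \code{minMaps} centroids).
#' @export
clusterMetric <- function(centroids, nShuffles = 1000, alpha = 0.05,
                          seed = 1L, minMaps = 3) {
  stopIfNot(all(c("name", "x", "y") %in% names(centroids)),
            "centroids needs columns name, x, y")
  disp <- function(xy) {
    ctr <- colMeans(xy)
    mean(sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2))
  }
  xyAll <- as.matrix(centroids[, c("x", "y")])
  out <- NULL
  withLocalSeed(seed, {
    for (nm in unique(centroids$name)) {
      sel <- centroids$name == nm
      n <- sum(sel)
      if (n < minMaps) {
        out <- rbind(out, data.frame(name = nm, n = n, Ck = NA_real_,
                                     pValue = NA_real_,
                                     significant = NA))
        next
      }
      obs <- disp(xyAll[sel, , drop = FALSE])
      null <- vapply(seq_len(nShuffles), function(i)
        disp(xyAll[sample(nrow(xyAll), n), , drop = FALSE]), numeric(1))
      Ck <- if (obs == 0) 0 else obs / mean(null)
      p <- mean(null <= obs)
      out <- rbind(out, data.frame(name = nm, n = n, Ck = Ck, pValue = p,
                                   significant = p < alpha))
    }
  })
  out
}
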
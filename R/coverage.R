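#' @include AllClasses.R utils.R fieldsign.R
NULL

## Shared grid geometry: cells of `resolutionDeg` anchored at the origin.
## Row r of the grid spans altitude [altMin + (r-1)*res, altMin + r*res).
coverageGridFrame <- function(extentDeg, resolutionDeg) {
  aziMin <- floor(extentDeg[1] / resolutionDeg) * resolutionDeg
  aziMax <- ceiling(extentDeg[2] / resolutionDeg) * resolutionDeg
  altMin <- floor(extentDeg[3] / resolutionDeg) * resolutionDeg
  altMax <- ceiling(extentDeg[4] / resolutionDeg) * resolutionDeg
  list(extent = c(aziMin, aziMax, altMin, altMax),
       nAlt = max(1L, as.integer(round((altMax - altMin) / resolutionDeg))),
       nAzi = max(1L, as.integer(round((aziMax - aziMin) / resolutionDeg))))
}

#' Visual-space coverage of a cortical patch
#'
#' Marks every visual-space cell that contains the preferred position of at
#' least one patch pixel (cell occupancy, not kernel density).
#'
#' @param mask logical cortical mask (e.g. from \code{\link{patchMask}}).
#' @param maps a \linkS4class{PositionMaps}.
#' @param resolutionDeg grid cell size (degrees; default 1).
#' @param extentDeg optional grid extent c(aziMin, aziMax, altMin, altMax);
#'   default tight around the occupied positions.
#' @return A \linkS4class{CoverageMask}; empty patches give an empty mask.
#' @export
patchCoverage <- function(mask, maps, resolutionDeg = 1, extentDeg = NULL) {
  idx <- which(mask & validMask(maps), arr.ind = TRUE)
  if (!nrow(idx)) {
    fr <- coverageGridFrame(if (is.null(extentDeg)) c(0, 1, 0, 1) else
      extentDeg, resolutionDeg)
    return(new("CoverageMask",
               grid = matrix(FALSE, fr$nAlt, fr$nAzi),
               resolutionDeg = resolutionDeg, extentDeg = fr$extent))
  }
  alt <- altitude(maps)[idx]; azi <- azimuth(maps)[idx]
  if (is.null(extentDeg))
    extentDeg <- c(min(azi), max(azi) + resolutionDeg / 2,
                   min(alt), max(alt) + resolutionDeg / 2)
  fr <- coverageGridFrame(extentDeg, resolutionDeg)
  ra <- floor((alt - fr$extent[3]) / resolutionDeg) + 1
  cz <- floor((azi - fr$extent[1]) / resolutionDeg) + 1
  ok <- ra >= 1 & ra <= fr$nAlt & cz >= 1 & cz <= fr$nAzi
  g <- matrix(FALSE, fr$nAlt, fr$nAzi)
  g[cbind(ra[ok], cz[ok])] <- TRUE
  new("CoverageMask", grid = g, resolutionDeg = resolutionDeg,
      extentDeg = fr$extent)
}

## Cell-center coordinates of a coverage grid.
coverageCellCenters <- function(mask) {
  res <- mask@resolutionDeg; e <- mask@extentDeg
  list(alt = e[3] + (seq_len(nrow(mask@grid)) - 0.5) * res,
       azi = e[1] + (seq_len(ncol(mask@grid)) - 0.5) * res)
}

#' Center of coverage
#'
#' Centroid of the occupied cells of a coverage mask, in degrees.
#'
#' @param mask a non-empty \linkS4class{CoverageMask}.
#' @return Named numeric: \code{altitude}, \code{azimuth} (degrees).
#' @export
centerOfCoverage <- function(mask) {
  stopIfNot(any(mask@grid), "coverage mask is empty")
  cc <- coverageCellCenters(mask)
  idx <- which(mask@grid, arr.ind = TRUE)
  c(altitude = mean(cc$alt[idx[, 1]]), azimuth = mean(cc$azi[idx[, 2]]))
}

#' Eccentricity map: angular distance from a reference position
#'
#' For a \linkS4class{PositionMaps} the result is an image over cortex; for
#' a \linkS4class{CoverageMask} an image over the visual grid.  The default
#' metric is Euclidean in (altitude, azimuth) degrees, matching flat-grid
#' coverage plots; great-circle distance on the sphere is available.
#'
#' @param x a \linkS4class{PositionMaps} or \linkS4class{CoverageMask}.
#' @param reference numeric c(altitude, azimuth) in degrees; typically the
#'   center of coverage of V1.
#' @param metric "euclidean" or "greatcircle".
#' @return A numeric matrix of non-negative distances (degrees).
#' @export
eccentricityOf <- function(x, reference,
                           metric = c("euclidean", "greatcircle")) {
  metric <- match.arg(metric)
  stopIfNot(all(is.finite(reference)), "reference must be finite")
  if (methods::is(x, "PositionMaps")) {
    alt <- altitude(x); azi <- azimuth(x)
  } else if (methods::is(x, "CoverageMask")) {
    cc <- coverageCellCenters(x)
    alt <- matrix(cc$alt, nrow(x@grid), ncol(x@grid))
    azi <- matrix(cc$azi, nrow(x@grid), ncol(x@grid), byrow = TRUE)
  } else stop("x must be a PositionMaps or CoverageMask")
  if (metric == "euclidean") {
    sqrt((alt - reference[1])^2 + (azi - reference[2])^2)
  } else {
    d2r <- pi / 180
    ca <- cos(alt * d2r) * cos(reference[1] * d2r)
    h <- sin((alt - reference[1]) * d2r / 2)^2 +
      ca * sin((azi - reference[2]) * d2r / 2)^2
    2 * asin(pmin(1, sqrt(h))) / d2r
  }
}

#' Pairwise coverage overlap and visual-field quadrant fractions
#'
#' All masks must share grid geometry.  Quadrants are defined around the
#' reference position (typically the center of coverage of V1): upper/lower
#' by altitude, nasal/temporal by azimuth (azimuth below the reference is
#' nasal).
#'
#' @param masks a named list of \linkS4class{CoverageMask}s on one grid.
#' @param reference numeric c(altitude, azimuth): quadrant division point.
#' @return A list: \code{overlapDeg2} (symmetric matrix of pairwise
#'   intersection areas in deg^2) and \code{quadrants} (data.frame of
#'   per-mask area fractions in the four quadrants).
#' @export
overlapAndQuadrants <- function(masks, reference) {
  stopIfNot(length(masks) >= 1, "need at least one mask")
  g1 <- masks[[1]]
  for (m in masks)
    stopIfNot(identical(m@extentDeg, g1@extentDeg) &&
                identical(dim(m@grid), dim(g1@grid)) &&
                m@resolutionDeg == g1@resolutionDeg,
              "all masks must share the same grid")
  n <- length(masks)
  cellArea <- g1@resolutionDeg^2
  ov <- matrix(0, n, n, dimnames = list(names(masks), names(masks)))
  for (a in seq_len(n)) for (b in seq_len(n))
    ov[a, b] <- sum(masks[[a]]@grid & masks[[b]]@grid) * cellArea
  cc <- coverageCellCenters(g1)
  upper <- matrix(cc$alt >= reference[1], nrow(g1@grid), ncol(g1@grid))
  nasal <- matrix(cc$azi < reference[2], nrow(g1@grid), ncol(g1@grid),
                  byrow = TRUE)
  quad <- t(vapply(masks, function(m) {
    tot <- sum(m@grid)
    if (tot == 0) return(c(upperNasal = 0, upperTemporal = 0,
                           lowerNasal = 0, lowerTemporal = 0))
    c(upperNasal = sum(m@grid & upper & nasal),
      upperTemporal = sum(m@grid & upper & !nasal),
      lowerNasal = sum(m@grid & !upper & nasal),
      lowerTemporal = sum(m@grid & !upper & !nasal)) / tot
  }, numeric(4)))
  list(overlapDeg2 = ov,
       quadrants = data.frame(name = names(masks), quad,
                              row.names = NULL))
}

#' Expand coverage by a receptive-field radius
#'
#' Morphological dilation of the coverage mask by a disk of the given radius
#' in degrees, emulating the outward spread of stimulus-evoked activity by
#' single-cell receptive fields.  The grid is padded so the expansion is
#' never clipped.
#'
#' @param mask a \linkS4class{CoverageMask}.
#' @param rfRadiusDeg receptive-field radius (degrees, >= 0).
#' @return A \linkS4class{CoverageMask} on the padded grid.
#' @export
expandCoverage <- function(mask, rfRadiusDeg) {
  stopIfNot(rfRadiusDeg >= 0, "rfRadiusDeg must be >= 0")
  res <- mask@resolutionDeg
  rPx <- rfRadiusDeg / res
  if (rPx == 0) return(mask)
  pad <- ceiling(rPx) + 1
  g <- matrix(FALSE, nrow(mask@grid) + 2 * pad, ncol(mask@grid) + 2 * pad)
  g[pad + seq_len(nrow(mask@grid)), pad + seq_len(ncol(mask@grid))] <-
    mask@grid
  ## a disk brush of the exact radius in cells
  rr <- ceiling(rPx)
  off <- expand.grid(dr = -rr:rr, dc = -rr:rr)
  off <- off[off$dr^2 + off$dc^2 <= rPx^2 + 1e-9, ]
  out <- matrix(FALSE, nrow(g), ncol(g))
  src <- which(g, arr.ind = TRUE)
  for (i in seq_len(nrow(off))) {
    rs <- src[, 1] + off$dr[i]; cs <- src[, 2] + off$dc[i]
    out[cbind(rs, cs)] <- TRUE
  }
  e <- mask@extentDeg
  new("CoverageMask", grid = out, resolutionDeg = res,
      extentDeg = c(e[1] - pad * res, e[2] + pad * res,
                    e[3] - pad * res, e[4] + pad * res))
}

#' Coverage summary for all patches of a segmentation
#'
#' @param pm a \linkS4class{PatchMap}.
#' @param maps the \linkS4class{PositionMaps} it came from.
#' @param resolutionDeg grid resolution (degrees).
#' @return A list: \code{masks} (named list of \linkS4class{CoverageMask}s
#'   on a common grid) and \code{summary} (data.frame with patch id, name,
#'   sign, area in deg^2 and coverage center).
#' @export
coverageByPatch <- function(pm, maps, resolutionDeg = 1) {
  v <- validMask(maps)
  extent <- c(min(azimuth(maps)[v]), max(azimuth(maps)[v]) + resolutionDeg,
              min(altitude(maps)[v]), max(altitude(maps)[v]) + resolutionDeg)
  ids <- pm@patches$id
  masks <- lapply(ids, function(i)
    patchCoverage(patchMask(pm, i), maps, resolutionDeg, extent))
  names(masks) <- ifelse(is.na(pm@patches$name), paste0("patch", ids),
                         pm@patches$name)
  ctr <- t(vapply(masks, function(m)
    if (any(m@grid)) centerOfCoverage(m) else c(NA_real_, NA_real_),
    numeric(2)))
  list(masks = masks,
       summary = data.frame(id = ids, name = pm@patches$name,
                            sign = pm@patches$sign,
                            areaDeg2 = vapply(masks, coverageArea,
                                              numeric(1)),
                            centerAltDeg = ctr[, 1], centerAziDeg = ctr[, 2],
                            row.names = NULL))
}
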
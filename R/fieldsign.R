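#' @include AllClasses.R utils.R
NULL

## NA-aware gradient: central differences where both neighbours are valid,
## one-sided at mask edges, NA where no valid neighbour exists.
maskedGradient <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(x, dr, dc) {
    out <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okR <- rs >= 1 & rs <= nr; okC <- cs >= 1 & cs <= nc
    out[okR, okC] <- x[rs[okR], cs[okC]]
    out
  }
  grad1 <- function(up, dn) {
    ## up = value one step back, dn = one step forward
    g <- (dn - up) / 2
    oneF <- is.na(up) & !is.na(dn)
    oneB <- !is.na(up) & is.na(dn)
    g[oneF] <- (dn - m)[oneF]
    g[oneB] <- (m - up)[oneB]
    g
  }
  list(drow = grad1(shift(m, -1, 0), shift(m, 1, 0)),
       dcol = grad1(shift(m, 0, -1), shift(m, 0, 1)))
}

#' Visual field sign map from position maps
#'
#' Per pixel, the sine of the angle between the local azimuth and altitude
#' gradients: \code{S = sin(angle(grad altitude) - angle(grad azimuth))},
#' equivalently the normalized cross product of the two gradients.  The
#' orientation convention makes V1-like (non-mirror) maps negative and their
#' mirror images positive.  Gradients are NA-aware central differences, so
#' the sign is defined up to the edge of the valid region; pixels with a
#' vanishing gradient are masked with value 0.
#'
#' @param maps a \linkS4class{PositionMaps}.
#' @return A \linkS4class{SignMap}.
#' @export
computeSignMap <- function(maps) {
  alt <- altitude(maps); azi <- azimuth(maps)
  ga <- maskedGradient(azi)
  gl <- maskedGradient(alt)
  cross <- ga$dcol * gl$drow - ga$drow * gl$dcol
  norm <- sqrt(ga$dcol^2 + ga$drow^2) * sqrt(gl$dcol^2 + gl$drow^2)
  s <- cross / norm
  zero <- is.finite(norm) & norm == 0
  s[zero] <- 0
  valid <- validMask(maps) & is.finite(s) & !zero
  s[!valid] <- NA_real_
  ## guard against rounding just past +-1
  s[valid] <- pmin(1, pmax(-1, s[valid]))
  new("SignMap", values = s, valid = valid, pixelSizeUm = maps@pixelSizeUm)
}

## Neighbour label summary for label growth: min and max positive label in
## the 8-neighbourhood of every pixel.
neighbourLabels <- function(L) {
  nr <- nrow(L); nc <- ncol(L)
  mn <- matrix(Inf, nr, nc); mx <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(0, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okR <- rs >= 1 & rs <= nr; okC <- cs >= 1 & cs <= nc
    sh[okR, okC] <- L[rs[okR], cs[okC]]
    pos <- sh > 0
    mn[pos] <- pmin(mn[pos], sh[pos])
    mx[pos] <- pmax(mx[pos], sh[pos])
  }
  mn[!is.finite(mn)] <- 0
  list(min = mn, max = mx)
}

## Thin touching labels to leave a one-pixel border: a labeled pixel with an
## 8-neighbour of a smaller positive label is cleared.  Deterministic.
thinLabelContacts <- function(L) {
  nb <- neighbourLabels(L)
  clear <- L > 0 & nb$min > 0 & nb$min < L
  L[clear] <- 0L
  L
}

## Border pixels: background pixels with at least two distinct positive
## labels in their 8-neighbourhood.
borderPixels <- function(L) {
  nb <- neighbourLabels(L)
  which(L == 0 & nb$max > nb$min & nb$min > 0, arr.ind = TRUE)
}

buildPatchMap <- function(L, raw, pixelSizeUm, names = NULL) {
  ids <- sort(setdiff(unique(as.vector(L)), 0L))
  ## compact, deterministic relabeling in order of first pixel occurrence
  newL <- matrix(0L, nrow(L), ncol(L))
  patches <- data.frame(id = integer(0), sign = integer(0),
                        nPixels = integer(0), name = character(0))
  for (i in seq_along(ids)) {
    mask <- L == ids[i]
    newL[mask] <- i
    sgn <- as.integer(sign(stats::median(raw[mask])))
    if (sgn == 0) sgn <- 1L
    patches <- rbind(patches, data.frame(
      id = i, sign = sgn, nPixels = sum(mask),
      name = if (is.null(names)) NA_character_ else names[i]))
  }
  b <- borderPixels(newL)
  new("PatchMap", labels = newL, patches = patches, raw = raw,
      borders = if (nrow(patches)) b else matrix(0L, 0, 2),
      pixelSizeUm = pixelSizeUm)
}

#' Binarize a sign map into a raw patch map
#'
#' The sign map is Gaussian filtered, thresholded at \code{signThreshold}
#' (pixels keep their sign, sub-threshold pixels become 0), cleaned with
#' open/close operations, and connected components (4-connectivity) are
#' labeled.  Components are then grown into the surrounding sub-threshold
#' (but valid) pixels, one pixel per iteration, so that adjacent patches end
#' up separated by a one-pixel border; growth stops where fronts of
#' different patches meet, and a final thinning pass guarantees the border.
#'
#' @param sign a \linkS4class{SignMap}.
#' @param params a \linkS4class{SegmentationParams}.
#' @return A raw \linkS4class{PatchMap} (before split/merge).
#' @export
binarizeSignMap <- function(sign, params = SegmentationParams()) {
  s <- sign@values
  valid <- sign@valid
  sigmaPx <- if (is.finite(sign@pixelSizeUm))
    params@signFilterSigmaUm / sign@pixelSizeUm else params@signFilterSigmaUm
  if (sigmaPx < 1 && params@signFilterSigmaUm > 0)
    message("sign-map filter sigma is below one pixel (",
            format(sigmaPx, digits = 2), " px); filtering has little effect")
  sf <- gaussianBlur(s, sigmaPx)
  sf[!valid | !is.finite(sf)] <- 0
  pos <- sf > params@signThreshold
  neg <- sf < -params@signThreshold
  if (params@openCloseRadiusPx > 0) {
    k <- discBrush(params@openCloseRadiusPx)
    clean <- function(m) {
      x <- EBImage::closing(EBImage::opening(m * 1, k), k)
      as.matrix(x) > 0.5
    }
    pos <- clean(pos); neg <- clean(neg)
  }
  raw <- matrix(0, nrow(s), ncol(s))
  raw[pos] <- 1; raw[neg] <- -1
  Lp <- as.matrix(EBImage::bwlabel(pos * 1))
  Ln <- as.matrix(EBImage::bwlabel(neg * 1))
  L <- Lp
  L[Ln > 0] <- Ln[Ln > 0] + max(Lp)
  L <- matrix(as.integer(L), nrow(L), ncol(L))
  ## grow labels into sub-threshold valid pixels
  for (iter in seq_len(params@growthIter)) {
    nb <- neighbourLabels(L)
    cand <- valid & L == 0 & nb$max > 0 & nb$min == nb$max
    if (!any(cand)) break
    L[cand] <- as.integer(nb$min[cand])
  }
  L <- thinLabelContacts(L)
  buildPatchMap(L, raw, sign@pixelSizeUm)
}

## Visual-space cell index of each pixel of a mask; cells are
## resolution-sized bins anchored at the origin.
cellIndices <- function(mask, maps, resolutionDeg) {
  idx <- which(mask & validMask(maps), arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  ca <- floor(altitude(maps)[idx] / resolutionDeg)
  cz <- floor(azimuth(maps)[idx] / resolutionDeg)
  list(idx = idx, cell = paste(ca, cz))
}

#' Redundancy of visual coverage between two patches
#'
#' Fraction of visual space represented by both patches: the overlap of the
#' two coverage masks divided by the smaller coverage area.
#'
#' @param maskA,maskB logical matrices (cortical pixel masks).
#' @param maps a \linkS4class{PositionMaps}.
#' @param resolutionDeg visual grid resolution (degrees).
#' @return A fraction in [0, 1]; 0 when either coverage is empty.
#' @export
coverageRedundancy <- function(maskA, maskB, maps, resolutionDeg = 1) {
  a <- cellIndices(maskA, maps, resolutionDeg)
  b <- cellIndices(maskB, maps, resolutionDeg)
  if (is.null(a) || is.null(b)) return(0)
  ca <- unique(a$cell); cb <- unique(b$cell)
  length(intersect(ca, cb)) / min(length(ca), length(cb))
}

#' Internal coverage redundancy of one patch
#'
#' Fraction of visual-space cells claimed by more than one disjoint cortical
#' sub-region of the patch: a cell is redundant when the patch pixels
#' mapping into it form two or more 8-connected components.
#'
#' @param mask logical cortical mask of the patch.
#' @param maps a \linkS4class{PositionMaps}.
#' @param resolutionDeg visual grid resolution (degrees).
#' @return A fraction in [0, 1].
#' @export
internalRedundancy <- function(mask, maps, resolutionDeg = 1) {
  ci <- cellIndices(mask, maps, resolutionDeg)
  if (is.null(ci)) return(0)
  groups <- split(seq_len(nrow(ci$idx)), ci$cell)
  red <- vapply(groups, function(g)
    nComponents8(ci$idx[g, 1], ci$idx[g, 2]) > 1, logical(1))
  mean(red)
}

## Eccentricity image over cortex: degrees from a reference visual position
## (default: centroid of the covered visual cells of all valid pixels).
corticalEccentricity <- function(maps, reference = NULL,
                                 resolutionDeg = 1) {
  if (is.null(reference)) {
    v <- validMask(maps)
    cells <- unique(data.frame(
      a = floor(altitude(maps)[v] / resolutionDeg),
      z = floor(azimuth(maps)[v] / resolutionDeg)))
    reference <- c((mean(cells$a) + 0.5) * resolutionDeg,
                   (mean(cells$z) + 0.5) * resolutionDeg)
  }
  sqrt((altitude(maps) - reference[1])^2 +
         (azimuth(maps) - reference[2])^2)
}

## Split one patch by watershed on the eccentricity image, seeded at its
## regional eccentricity minima (prominence tolerance in degrees).
watershedSplit <- function(mask, ecc, prominenceDeg) {
  e <- ecc
  e[!mask | !is.finite(e)] <- NA
  if (all(is.na(e))) return(NULL)
  inv <- max(e, na.rm = TRUE) - e + prominenceDeg
  inv[is.na(inv)] <- 0
  w <- as.matrix(EBImage::watershed(inv, tolerance = prominenceDeg))
  w[!mask] <- 0
  ids <- setdiff(unique(as.vector(w)), 0)
  if (length(ids) < 2) return(NULL)
  lapply(ids, function(i) w == i)
}

#' Split and merge raw patches by visual-coverage redundancy
#'
#' Iterates to a fixed point: patches whose internal redundancy exceeds the
#' threshold are split by a watershed on the visual eccentricity map seeded
#' at its regional minima; adjacent same-sign patches with redundancy below
#' the threshold are merged (pairs processed in order of increasing
#' redundancy); patches below the minimum pixel count are discarded.
#'
#' @param pm a raw \linkS4class{PatchMap} from \code{\link{binarizeSignMap}}.
#' @param maps the \linkS4class{PositionMaps} the patches came from.
#' @param params a \linkS4class{SegmentationParams}.
#' @param eccReference optional reference visual position (altitude,
#'   azimuth) for the eccentricity map; default is the centroid of the
#'   combined coverage.
#' @return A \linkS4class{PatchMap} satisfying the fixed-point condition.
#' @export
splitMergePatches <- function(pm, maps, params = SegmentationParams(),
                              eccReference = NULL) {
  res <- params@coverageResolutionDeg
  ecc <- corticalEccentricity(maps, eccReference, res)
  L <- pm@labels
  masks <- lapply(pm@patches$id, function(i) L == i)
  signs <- pm@patches$sign
  unsplittable <- rep(FALSE, length(masks))
  for (iter in seq_len(params@maxIter)) {
    changed <- FALSE
    ## -- split pass
    i <- 1
    while (i <= length(masks)) {
      if (!unsplittable[i] &&
          internalRedundancy(masks[[i]], maps, res) >
            params@redundancyThreshold) {
        parts <- watershedSplit(masks[[i]], ecc,
                                params@watershedProminenceDeg)
        if (is.null(parts)) {
          unsplittable[i] <- TRUE
        } else {
          sgn <- signs[i]
          masks <- c(masks[-i], parts)
          signs <- c(signs[-i], rep(sgn, length(parts)))
          unsplittable <- c(unsplittable[-i], rep(FALSE, length(parts)))
          changed <- TRUE
          next
        }
      }
      i <- i + 1
    }
    ## -- merge pass: same-sign adjacent pairs, increasing redundancy
    repeat {
      n <- length(masks)
      pairs <- NULL
      for (a in seq_len(n)) for (b in seq_len(n)) {
        if (b <= a || signs[a] != signs[b]) next
        near <- dilateMask(masks[[a]], params@borderWidthPx + 1)
        if (!any(near & masks[[b]])) next
        red <- coverageRedundancy(masks[[a]], masks[[b]], maps, res)
        if (red < params@redundancyThreshold)
          pairs <- rbind(pairs, data.frame(a = a, b = b, red = red))
      }
      if (is.null(pairs)) break
      pairs <- pairs[order(pairs$red, pairs$a, pairs$b), ]
      a <- pairs$a[1]; b <- pairs$b[1]
      u <- masks[[a]] | masks[[b]]
      ## absorb the border line between the two merged patches
      gap <- dilateMask(masks[[a]], params@borderWidthPx) &
        dilateMask(masks[[b]], params@borderWidthPx) & validMask(maps)
      others <- Reduce("|", masks[-c(a, b)], matrix(FALSE, nrow(u), ncol(u)))
      u <- u | (gap & !others)
      sgn <- signs[a]
      masks <- c(masks[-c(a, b)], list(u))
      signs <- c(signs[-c(a, b)], sgn)
      unsplittable <- c(unsplittable[-c(a, b)], FALSE)
      changed <- TRUE
    }
    ## -- discard small patches
    keep <- vapply(masks, sum, numeric(1)) >= params@minPatchPixels
    if (!all(keep)) {
      masks <- masks[keep]; signs <- signs[keep]
      unsplittable <- unsplittable[keep]
      changed <- TRUE
    }
    if (!changed) break
    if (iter == params@maxIter)
      stop("split/merge did not reach a fixed point after ",
           params@maxIter, " iterations (", length(masks), " patches)")
  }
  ## rebuild label image; deterministic order by first pixel index
  if (!length(masks))
    return(new("PatchMap", labels = matrix(0L, nrow(L), ncol(L)),
               patches = data.frame(id = integer(0), sign = integer(0),
                                    nPixels = integer(0),
                                    name = character(0)),
               raw = pm@raw, borders = matrix(0L, 0, 2),
               pixelSizeUm = pm@pixelSizeUm))
  ord <- order(vapply(masks, function(m) which(m)[1], numeric(1)))
  L2 <- matrix(0L, nrow(L), ncol(L))
  for (i in seq_along(ord)) L2[masks[[ord[i]]]] <- i
  L2 <- thinLabelContacts(L2)
  rawSigned <- pm@raw
  out <- buildPatchMap(L2, rawSigned, pm@pixelSizeUm)
  ## signs from construction, not from the raw map (merged/grown pixels)
  out@patches$sign <- as.integer(signs[ord])
  methods::validObject(out)
  out
}

#' Segment position maps into field-sign patches
#'
#' The full border-identification pipeline: sign map, filtering and
#' thresholding, open/close cleanup, component labeling and growth to
#' one-pixel borders, then redundancy-driven split/merge and small-patch
#' removal.  Deterministic for fixed inputs and parameters.
#'
#' @param maps a \linkS4class{PositionMaps}.
#' @param params a \linkS4class{SegmentationParams}.
#' @param eccReference optional eccentricity reference, see
#'   \code{\link{splitMergePatches}}.
#' @return A \linkS4class{PatchMap}.
#' @examples
#' maps <- atlasPositionMaps(buildDefaultAtlas())
#' pm <- segmentPatches(maps)
#' patchTable(pm)
#' @export
segmentPatches <- function(maps, params = SegmentationParams(),
                           eccReference = NULL) {
  sm <- computeSignMap(maps)
  raw <- binarizeSignMap(sm, params)
  if (!nrow(raw@patches)) return(raw)
  splitMergePatches(raw, maps, params, eccReference)
}

#' Extract the mask of one patch
#'
#' @param pm a \linkS4class{PatchMap}.
#' @param id patch id (or name, if names were assigned).
#' @return A logical matrix.
#' @export
patchMask <- function(pm, id) {
  if (is.character(id)) {
    hit <- match(id, pm@patches$name)
    stopIfNot(!is.na(hit), paste("no patch named", id))
    id <- pm@patches$id[hit]
  }
  pm@labels == id
}
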
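#' @include AllClasses.R utils.R fieldsign.R
NULL

## Shift a 3-D array by (dx, dy, dz), padding with `fill`.
shift3 <- function(a, dx, dy, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- seq_len(d[1]) + dx; sy <- seq_len(d[2]) + dy; sz <- seq_len(d[3]) + dz
  ox <- sx >= 1 & sx <= d[1]; oy <- sy >= 1 & sy <= d[2]
  oz <- sz >= 1 & sz <= d[3]
  out[ox, oy, oz] <- a[sx[ox], sy[oy], sz[oz]]
  out
}

#' Weighted source center-of-mass field from injection experiments
#'
#' Pools tracer experiments into a per-voxel estimate of the source location
#' most strongly connected to that voxel: the center of mass of the
#' injection centers, weighted by the normalized projection strength
#' \code{W = Ft / Fs} (projection density over injection density).  Voxels
#' with zero summed weight are undefined.  The field is invariant to
#' scaling any single experiment's Ft and Fs by a common constant.
#'
#' @param experiments list; each element has \code{sourceCenter} (length-3
#'   numeric), \code{Fs} (positive scalar injection density) and \code{Ft}
#'   (3-D array of projection density, common grid).
#' @return A \linkS4class{ProjectionField}.
#' @export
weightedSourceField <- function(experiments) {
  stopIfNot(length(experiments) >= 1, "need at least one experiment")
  d <- dim(experiments[[1]]$Ft)
  wSum <- array(0, d)
  num <- array(0, c(d, 3))
  for (ex in experiments) {
    stopIfNot(identical(dim(ex$Ft), d), "experiments must share one grid")
    stopIfNot(ex$Fs > 0, "injection density must be positive")
    stopIfNot(all(ex$Ft >= 0), "projection density must be non-negative")
    w <- ex$Ft / ex$Fs
    wSum <- wSum + w
    for (k in 1:3) num[, , , k] <- num[, , , k] + w * ex$sourceCenter[k]
  }
  L <- array(NA_real_, c(d, 3))
  pos <- wSum > 0
  for (k in 1:3) {
    lk <- array(NA_real_, d)
    lk[pos] <- num[, , , k][pos] / wSum[pos]
    L[, , , k] <- lk
  }
  new("ProjectionField", L = L, weightSum = wSum)
}

#' Solve the normalized cortical depth field
#'
#' Solves the discrete Laplace equation on the cortex volume with Dirichlet
#' boundary conditions 0 on the pia and 1 on the white matter, by red-black
#' successive over-relaxation; equipotential surfaces of the solution are
#' the normalized-depth surfaces and its gradient defines the streamlines
#' used for surface projection.
#'
#' @param cortexMask,piaMask,wmMask logical 3-D arrays; pia and wm must be
#'   non-empty and disjoint, cortex connects them.
#' @param tol convergence tolerance on the maximum update (default 1e-6).
#' @param maxIter iteration cap.
#' @return A \linkS4class{DepthField}.
#' @export
solveDepthField <- function(cortexMask, piaMask, wmMask, tol = 1e-6,
                            maxIter = 50000) {
  stopIfNot(any(piaMask) && any(wmMask), "pia and wm masks must be non-empty")
  stopIfNot(!any(piaMask & wmMask), "pia and wm masks overlap")
  domain <- cortexMask | piaMask | wmMask
  ## 6-connectivity flood fill from one voxel must reach the whole domain
  seedIdx <- which(domain)[1]
  reach <- array(FALSE, dim(domain)); reach[seedIdx] <- TRUE
  repeat {
    grown <- reach
    for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1)))
      grown <- grown | shift3(reach, sh[1], sh[2], sh[3], fill = FALSE)
    grown <- grown & domain
    if (identical(grown, reach)) break
    reach <- grown
  }
  stopIfNot(all(reach[domain]), "cortex mask is disconnected")
  d <- dim(domain)
  phi <- array(0.5, d)
  phi[!domain] <- NA_real_
  phi[piaMask] <- 0; phi[wmMask] <- 1
  free <- domain & !piaMask & !wmMask
  xi <- slice.index(phi, 1); yi <- slice.index(phi, 2)
  zi <- slice.index(phi, 3)
  red <- ((xi + yi + zi) %% 2 == 0) & free
  black <- ((xi + yi + zi) %% 2 == 1) & free
  n <- max(d)
  omega <- 2 / (1 + sin(pi / n))
  sweepOnce <- function(phi, mask) {
    s <- array(0, d); cnt <- array(0, d)
    for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))) {
      v <- shift3(phi, sh[1], sh[2], sh[3], fill = NA)
      ok <- !is.na(v)
      s[ok] <- s[ok] + v[ok]
      cnt <- cnt + ok
    }
    upd <- mask & cnt > 0
    newv <- s[upd] / cnt[upd]
    delta <- omega * (newv - phi[upd])
    phi[upd] <- phi[upd] + delta
    list(phi = phi, maxDelta = if (length(delta)) max(abs(delta)) else 0)
  }
  for (it in seq_len(maxIter)) {
    a <- sweepOnce(phi, red); phi <- a$phi
    b <- sweepOnce(phi, black); phi <- b$phi
    if (max(a$maxDelta, b$maxDelta) < tol) break
    if (it == maxIter)
      warning("depth field did not reach tolerance ", tol, " after ",
              maxIter, " iterations")
  }
  phi <- array(pmin(1, pmax(0, phi)), d)
  new("DepthField", depth = phi, cortexMask = domain)
}

## Trilinear sampling of a 3-D array at fractional coordinates.
trilinearSample <- function(a, p) {
  f0 <- floor(p); fr <- p - f0
  d <- dim(a)
  if (any(f0 < 1) || any(f0 + 1 > d)) return(NA_real_)
  v <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
    v <- v + w * a[f0[1] + dx, f0[2] + dy, f0[3] + dz]
  }
  v
}

#' Project the source field to the pial surface
#'
#' For each surface column, a streamline is followed from the shallowest
#' cortex voxel along the normalized depth gradient; among the voxels it
#' traverses within the given depth range (default 0.1-0.5), the one with
#' the greatest summed projection strength is selected (ties: the
#' shallowest wins) and its source-location vector is copied to the
#' surface.  The surface map is then viewed orthographically along the
#' depth axis, yielding separate anterior-posterior and medial-lateral
#' coordinate maps.
#'
#' @param field a \linkS4class{ProjectionField}.
#' @param depthField a \linkS4class{DepthField} on the same grid.
#' @param depthRange numeric pair: normalized depth window.
#' @param stepVox streamline integration step (voxels).
#' @return A list: \code{AP} and \code{ML} (matrices over the x, y surface
#'   grid; NA where no connected voxel lies in range) and \code{weight}
#'   (selected summed projection strength).
#' @export
projectToSurface <- function(field, depthField, depthRange = c(0.1, 0.5),
                             stepVox = 0.5) {
  d <- dim(field@weightSum)
  stopIfNot(identical(dim(depthField@depth), d),
            "field and depth grids differ")
  depth <- depthField@depth
  dm <- depth; dm[is.na(dm)] <- 0.5   # neutral fill for gradient sampling
  gx <- (shift3(dm, 1, 0, 0, NA) - shift3(dm, -1, 0, 0, NA)) / 2
  gy <- (shift3(dm, 0, 1, 0, NA) - shift3(dm, 0, -1, 0, NA)) / 2
  gz <- (shift3(dm, 0, 0, 1, NA) - shift3(dm, 0, 0, -1, NA)) / 2
  AP <- matrix(NA_real_, d[1], d[2]); ML <- AP; WT <- AP
  for (ix in seq_len(d[1])) for (iy in seq_len(d[2])) {
    col <- depth[ix, iy, ]
    if (all(is.na(col))) next
    iz <- which.min(col)
    p <- c(ix, iy, iz)
    bestW <- -Inf; bestL <- c(NA_real_, NA_real_, NA_real_)
    for (step in seq_len(ceiling(d[3] / stepVox) * 4)) {
      vi <- round(p)
      if (any(vi < 1) || any(vi > d)) break
      dep <- depth[vi[1], vi[2], vi[3]]
      if (is.na(dep) || dep > depthRange[2] + 0.05) break
      if (dep >= depthRange[1] && dep <= depthRange[2]) {
        w <- field@weightSum[vi[1], vi[2], vi[3]]
        if (is.finite(w) && w > bestW && w > 0) {
          bestW <- w
          bestL <- field@L[vi[1], vi[2], vi[3], ]
        }
      }
      g <- c(trilinearSample(gx, p), trilinearSample(gy, p),
             trilinearSample(gz, p))
      if (any(is.na(g)) || sqrt(sum(g^2)) < 1e-9) {
        p <- p + c(0, 0, stepVox)     # degenerate gradient: descend
      } else {
        p <- p + stepVox * g / sqrt(sum(g^2))
      }
    }
    if (is.finite(bestW)) {
      AP[ix, iy] <- bestL[1]; ML[ix, iy] <- bestL[2]; WT[ix, iy] <- bestW
    }
  }
  list(AP = AP, ML = ML, weight = WT)
}

#' Projection sign map and borders from surface maps
#'
#' The anterior-posterior and medial-lateral source-coordinate maps are
#' Gaussian filtered and combined exactly as altitude and azimuth maps are
#' in functional mapping, giving the projection-based field sign map; the
#' border-identification routine is then run at two thresholds, the
#' stricter one (0.2) for conservative borders and the lower one (0.1) to
#' close gaps the stricter threshold can leave between areas.
#'
#' @param surface list with \code{AP} and \code{ML} matrices (from
#'   \code{\link{projectToSurface}}).
#' @param pixelSizeUm voxel size of the surface grid (um; default 50).
#' @param mapSigmaUm Gaussian sigma for filtering the coordinate maps (um).
#' @param signSigmaUm Gaussian sigma for filtering the sign map (um).
#' @param thresholds two sign thresholds (default 0.2 and 0.1).
#' @param params base \linkS4class{SegmentationParams} for the border
#'   routine (the sign filter and thresholds above override its fields).
#' @return A list: \code{sign} (\linkS4class{SignMap}), \code{patchesHigh}
#'   and \code{patchesLow} (\linkS4class{PatchMap}s at the two thresholds).
#' @export
projectionSignMap <- function(surface, pixelSizeUm = 50, mapSigmaUm = 43,
                              signSigmaUm = 130, thresholds = c(0.2, 0.1),
                              params = SegmentationParams(
                                minPatchPixels = 30,
                                coverageResolutionDeg = 2)) {
  sg <- mapSigmaUm / pixelSizeUm
  AP <- gaussianBlur(surface$AP, sg)
  ML <- gaussianBlur(surface$ML, sg)
  maps <- PositionMaps(altitude = AP, azimuth = ML,
                       valid = is.finite(AP) & is.finite(ML),
                       pixelSizeUm = pixelSizeUm)
  sm <- computeSignMap(maps)
  segAt <- function(thr) {
    p <- params
    p@signThreshold <- thr
    p@signFilterSigmaUm <- signSigmaUm
    raw <- binarizeSignMap(sm, p)
    if (nrow(raw@patches)) splitMergePatches(raw, maps, p) else raw
  }
  list(sign = sm, patchesHigh = segAt(thresholds[1]),
       patchesLow = segAt(thresholds[2]))
}

#' Simulate retinotopically organized injection experiments
#'
#' Builds a synthetic stand-in for a tracer data set: injections tile a
#' source ("V1") sheet and each experiment's projection density peaks at
#' target voxels whose retinotopic label matches the injection site.  The
#' target sheet contains a direct zone (preserved orientation) and a
#' mirrored zone beyond \code{mirrorX}, so the derived projection sign map
#' has two opposite-sign patches.
#'
#' @param dims volume dimensions c(x, y, z).
#' @param nGrid injections form an nGrid x nGrid lattice over the source.
#' @param sigmaVox spatial spread of the projection density (voxels).
#' @param depthZ z-slab carrying projection density.
#' @param mirrorX x beyond which the target map is mirrored.
#' @param seed reserved for future stochastic variants (unused; the
#'   construction is deterministic).
#' @return A list: \code{experiments} (for
#'   \code{\link{weightedSourceField}}), \code{truthAP}, \code{truthML}
#'   (ground-truth source-coordinate maps over the surface grid), and
#'   \code{masks} (pia/cortex/wm logical arrays for the depth solver).
#' @export
simulateProjectionExperiments <- function(dims = c(40L, 40L, 12L),
                                          nGrid = 6, sigmaVox = 2,
                                          depthZ = 3:6, mirrorX = 20.5,
                                          seed = 1L) {
  srcX <- seq(5, 19, length.out = nGrid)
  srcY <- seq(14, 27, length.out = nGrid)
  xi <- slice.index(array(0, dims), 1)
  yi <- slice.index(array(0, dims), 2)
  zi <- slice.index(array(0, dims), 3)
  ## ground-truth source coordinates per target column
  tx <- matrix(rep(seq_len(dims[1]), dims[2]), dims[1], dims[2])
  ty <- matrix(rep(seq_len(dims[2]), each = dims[1]), dims[1], dims[2])
  truthAP <- ifelse(tx <= mirrorX, tx, 2 * mirrorX - tx)
  truthML <- ty
  inTarget <- tx >= 5 & tx <= 36 & ty >= 14 & ty <= 27 &
    truthAP >= min(srcX) & truthAP <= max(srcX)
  truthAP[!inTarget] <- NA; truthML[!inTarget] <- NA
  experiments <- list()
  for (sx in srcX) for (sy in srcY) {
    ft <- array(0, dims)
    dens <- exp(-((truthAP - sx)^2 + (truthML - sy)^2) / (2 * sigmaVox^2))
    dens[is.na(dens)] <- 0
    for (z in depthZ) ft[, , z] <- dens
    experiments[[length(experiments) + 1]] <-
      list(sourceCenter = c(sx, sy, mean(depthZ)), Fs = 1, Ft = ft)
  }
  pia <- zi == 1
  wm <- zi == dims[3]
  cortex <- zi > 1 & zi < dims[3]
  list(experiments = experiments, truthAP = truthAP, truthML = truthML,
       masks = list(pia = pia, cortex = cortex, wm = wm))
}
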
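#' @include AllClasses.R utils.R
NULL

areaFromRect <- function(dims, rows, cols, transform, amplitude = 1) {
  mask <- matrix(FALSE, dims[1], dims[2])
  mask[rows, cols] <- TRUE
  list(mask = mask, transform = transform, amplitude = amplitude)
}

#' Build the default ground-truth cortical atlas
#'
#' A central V1-like area (negative field sign) flanked by four mirror-image
#' areas of positive sign — lateral (LM-like), medial (PM-like), anterior
#' (RL-like) and posterior (P-like) — arranged as in the stereotyped mouse
#' map.  Each area carries an invertible affine transform from cortical pixel
#' coordinates to visual degrees; mirrored neighbours continue the V1 map
#' across the shared border with reversed chirality, so adjacent areas have
#' opposite field sign by construction.  Visual spans are chosen so that the
#' cortical sampling step is below one degree per pixel in both axes, giving
#' gap-free visual coverage at the default one-degree grid.
#'
#' @param dims image dimensions c(rows, cols); the default 96 x 96 leaves a
#'   baseline-only margin around the areas.
#' @param pixelSizeUm cortical pixel size (um).
#' @param amplitudes optional named numeric vector of relative response
#'   amplitudes per area (default 1 everywhere).
#' @param v1Only if TRUE, return a single-area atlas (a uniform-gradient
#'   map), useful for focused tests.
#' @return A \linkS4class{CorticalAtlas} with areas V1, LM, PM, RL, P.
#'   V1 covers roughly azimuth 0-42 and altitude -16..17 degrees; each
#'   neighbour mirrors a sub-rectangle of that range.
#' @examples
#' atlas <- buildDefaultAtlas()
#' fieldSign(atlas)
#' @export
buildDefaultAtlas <- function(dims = c(96L, 96L), pixelSizeUm = 25,
                              amplitudes = NULL, v1Only = FALSE) {
  dims <- as.integer(dims)
  stopIfNot(all(dims >= 96), "default layout needs at least 96 x 96 pixels")
  ## V1 lattice: rows 25..72, cols 25..72.  Steps below one degree per
  ## pixel give gap-free one-degree coverage; the small offsets keep the
  ## rectangle clear of visual-grid cell edges so occupancy areas match
  ## the analytic rectangle.
  sAz <- 0.9        # deg per pixel along azimuth
  sAl <- 0.7        # deg per pixel along altitude
  tr <- function(a11, a12, b1, a21, a22, b2)
    matrix(c(a11, a21, a12, a22, b1, b2), 2, 3)
  ## azimuth = 0.9 (col - 25) + 0.05; altitude = 16.95 - 0.7 (row - 25)
  v1 <- tr(sAz, 0, 0.05 - 25 * sAz, 0, -sAl, 16.95 + 25 * sAl)
  areas <- list(V1 = areaFromRect(dims, 25:72, 25:72, v1))
  if (!v1Only) {
    ## LM: lateral, azimuth mirrored about the shared edge at col 72/73
    lm <- tr(-sAz, 0, 41.45 + 73 * sAz, 0, -sAl, 16.95 + 25 * sAl)
    ## PM: medial, azimuth mirrored about col 24/25
    pm <- tr(-sAz, 0, 0.05 + 25 * sAz, 0, -sAl, 16.95 + 25 * sAl)
    ## RL: anterior, altitude mirrored about row 24/25
    rl <- tr(sAz, 0, 0.05 - 25 * sAz, 0, sAl, 16.95 - 25 * sAl)
    ## P: posterior, altitude mirrored about row 72/73
    pp <- tr(sAz, 0, 0.05 - 25 * sAz, 0, sAl, -15.95 - 72 * sAl)
    areas$LM <- areaFromRect(dims, 27:70, 73:92, lm)
    areas$PM <- areaFromRect(dims, 27:70, 5:24, pm)
    areas$RL <- areaFromRect(dims, 5:24, 27:70, rl)
    areas$P <- areaFromRect(dims, 73:92, 27:70, pp)
  }
  if (!is.null(amplitudes))
    for (nm in names(amplitudes))
      if (nm %in% names(areas)) areas[[nm]]$amplitude <- amplitudes[[nm]]
  new("CorticalAtlas", dims = dims, pixelSizeUm = pixelSizeUm, areas = areas)
}

#' Ground-truth position maps of an atlas
#'
#' Applies each area's retinotopic transform to its pixels, yielding the
#' noise-free altitude/azimuth maps the simulator and the recovery tests use
#' as reference.
#'
#' @param atlas a \linkS4class{CorticalAtlas}.
#' @return A \linkS4class{PositionMaps}; pixels outside all areas are
#'   invalid, amplitude equals each area's relative amplitude.
#' @export
atlasPositionMaps <- function(atlas) {
  alt <- matrix(NA_real_, atlas@dims[1], atlas@dims[2])
  azi <- alt
  amp <- matrix(0, atlas@dims[1], atlas@dims[2])
  for (a in atlas@areas) {
    idx <- which(a$mask, arr.ind = TRUE)
    va <- a$transform %*% rbind(idx[, 2], idx[, 1], 1)
    azi[idx] <- va[1, ]
    alt[idx] <- va[2, ]
    amp[idx] <- a$amplitude
  }
  PositionMaps(altitude = alt, azimuth = azi, amplitude = amp,
               valid = is.finite(alt), pixelSizeUm = atlas@pixelSizeUm)
}

#' Catalogue of retinotopically organized regions of mouse cortex
#'
#' The twelve published visual areas plus the four additional patches mapped
#' with GCaMP6 fluorescence (MMA, MMP, RLL and the retrosplenial patch RS),
#' with their field signs — sixteen distinct retinotopically organized
#' regions in all.
#'
#' @return A data.frame with columns \code{name}, \code{sign} (+1/-1) and
#'   \code{status} ("published" or "new").
#' @examples
#' nrow(mouseVisualAreas())  # 16
#' @export
mouseVisualAreas <- function() {
  published <- data.frame(
    name = c("V1", "LM", "LI", "AL", "LLA", "RL", "A", "AM", "PM", "M", "P",
             "POR"),
    sign = c(-1, 1, -1, -1, 1, 1, -1, -1, 1, 1, 1, -1),
    status = "published")
  new <- data.frame(name = c("MMA", "MMP", "RLL", "RS"),
                    sign = c(1, -1, -1, 1),
                    status = "new")
  rbind(published, new)
}
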
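#' @include AllGenerics.R
NULL

#' Altitude component of a map object
#'
#' @param x a \linkS4class{PositionMaps} or \linkS4class{CorticalAtlas} object.
#' @return A numeric matrix of altitudes in visual degrees (NA where invalid).
#' @export
setGeneric("altitude", function(x) standardGeneric("altitude"))

#' Azimuth component of a map object
#'
#' @param x a \linkS4class{PositionMaps} or \linkS4class{CorticalAtlas} object.
#' @return A numeric matrix of azimuths in visual degrees (NA where invalid).
#' @export
setGeneric("azimuth", function(x) standardGeneric("azimuth"))

#' First-harmonic response amplitude of a position map
#'
#' @param x a \linkS4class{PositionMaps} object.
#' @return A numeric matrix of per-pixel response amplitudes.
#' @export
setGeneric("amplitudeMap", function(x) standardGeneric("amplitudeMap"))

#' Per-pixel validity mask
#'
#' @param x a map-like object carrying a validity mask.
#' @return A logical matrix.
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' Label image of a segmentation
#'
#' @param x a \linkS4class{PatchMap} or \linkS4class{CorticalAtlas}.
#' @return An integer matrix; 0 denotes background/border, positive values
#'   are patch ids.
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))

#' Patch metadata table
#'
#' @param x a \linkS4class{PatchMap}.
#' @return A data.frame with one row per patch (id, sign, n pixels, name).
#' @export
setGeneric("patchTable", function(x) standardGeneric("patchTable"))

#' Covered area of a coverage mask, in square degrees
#'
#' @param x a \linkS4class{CoverageMask}.
#' @return Numeric scalar, \code{sum(grid) * resolution^2}.
#' @export
setGeneric("coverageArea", function(x) standardGeneric("coverageArea"))

#' Grid resolution in degrees per cell
#'
#' @param x a \linkS4class{CoverageMask}.
#' @return Numeric scalar.
#' @export
setGeneric("gridResolution", function(x) standardGeneric("gridResolution"))

#' Movie pixel data
#'
#' @param x a \linkS4class{Movie}.
#' @return The trials x time x rows x cols array.
#' @export
setGeneric("movieData", function(x) standardGeneric("movieData"))

#' Frame rate in Hz
#'
#' @param x a \linkS4class{Movie}.
#' @return Numeric scalar.
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' Field sign values
#'
#' @param x a \linkS4class{SignMap}, \linkS4class{PatchMap} patch table, or
#'   \linkS4class{CorticalAtlas}.
#' @return For a SignMap, a numeric matrix in [-1, 1]; for an atlas, the
#'   named vector of ground-truth signs.
#' @export
setGeneric("fieldSign", function(x) standardGeneric("fieldSign"))
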
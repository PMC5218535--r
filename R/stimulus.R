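#' @include AllClasses.R utils.R
NULL

## 3-D unit vectors of the coordinate frame: X forward along the midline,
## Y lateral (toward the stimulated eye), Z up.  The perpendicular from the
## eye to the monitor points at azimuth (90 - midline angle) and altitude 0.

monitorBasis <- function(geom) {
  a0 <- (90 - geom@midlineAngleDeg) * pi / 180
  list(perp = c(cos(a0), sin(a0), 0),
       eh = c(-sin(a0), cos(a0), 0),   # +u increases azimuth
       ev = c(0, 0, 1))                # +v increases altitude
}

#' Spherical correction: monitor point to visual coordinates
#'
#' Converts a point on the planar monitor, given in centimetres within the
#' monitor plane relative to the foot of the perpendicular from the eye, to
#' spherical visual coordinates.  Convention: altitude is the latitude,
#' \code{asin(z / |v|)}, of the eye-to-point ray; azimuth is the longitude
#' about the vertical axis through the eye, \code{atan2} of the lateral over
#' the forward component.  Azimuth 0 is the midline, positive temporal;
#' altitude 0 is the horizontal plane through the eyes, positive above.
#' Under this convention a purely vertical displacement on the monitor
#' changes altitude but never azimuth.
#'
#' @param u,v numeric vectors: horizontal and vertical displacement (cm)
#'   within the monitor plane from the perpendicular foot; +u toward larger
#'   azimuth, +v upward.
#' @param geom a \linkS4class{MonitorGeometry}.
#' @return A data.frame with columns \code{altitude} and \code{azimuth}
#'   (degrees).
#' @examples
#' sphericalCorrect(0, 0, MonitorGeometry())  # altitude 0, azimuth 60
#' @export
sphericalCorrect <- function(u, v, geom = MonitorGeometry()) {
  stopIfNot(length(u) == length(v), "u and v must have equal length")
  stopIfNot(geom@distanceCm > 0, "monitor point behind the eye plane")
  b <- monitorBasis(geom)
  d <- geom@distanceCm
  px <- d * b$perp[1] + u * b$eh[1] + v * b$ev[1]
  py <- d * b$perp[2] + u * b$eh[2] + v * b$ev[2]
  pz <- d * b$perp[3] + u * b$eh[3] + v * b$ev[3]
  nrm <- sqrt(px^2 + py^2 + pz^2)
  data.frame(altitude = asin(pz / nrm) * 180 / pi,
             azimuth = atan2(py, px) * 180 / pi)
}

#' Bar-center trajectory for one sweep direction
#'
#' The repetition period comes directly from the repeat frequency of the
#' stimulus (1/0.043 s for horizontal, 1/0.048 s for vertical sweeps); the
#' bar traverses the monitor extent plus one bar width (so that the leading
#' and trailing edges clear the screen) at the sweep speed and is off screen
#' for the remainder of the period.
#'
#' @param spec a \linkS4class{CheckerboardSpec}.
#' @param geom a \linkS4class{MonitorGeometry}.
#' @param direction one of \code{"N2T"} (nasal to temporal), \code{"T2N"},
#'   \code{"D2U"} (lower to upper field), \code{"U2D"}.
#' @return A \linkS4class{BarTrajectory}.
#' @export
barTrajectory <- function(spec = CheckerboardSpec(), geom = MonitorGeometry(),
                          direction = c("N2T", "T2N", "D2U", "U2D")) {
  direction <- match.arg(direction)
  horiz <- direction %in% c("N2T", "T2N")
  ext <- if (horiz) geom@azimuthExtentDeg else geom@altitudeExtentDeg
  lo <- ext[1] - spec@barWidthDeg / 2
  hi <- ext[2] + spec@barWidthDeg / 2
  span <- hi - lo
  sweepDur <- span / spec@sweepSpeedDegPerS
  period <- 1 / (if (horiz) spec@repeatFreqAzimuthHz else
                   spec@repeatFreqAltitudeHz)
  if (sweepDur > period)
    stop("sweep duration exceeds the repetition period; ",
         "reduce the extent or increase the sweep speed")
  fwd <- direction %in% c("N2T", "D2U")
  new("BarTrajectory",
      axis = if (horiz) "azimuth" else "altitude",
      direction = direction,
      startDeg = if (fwd) lo else hi,
      speedDegPerS = if (fwd) spec@sweepSpeedDegPerS else
        -spec@sweepSpeedDegPerS,
      periodS = period, sweepDurationS = sweepDur)
}

#' Bar-center position at given times
#'
#' @param traj a \linkS4class{BarTrajectory}.
#' @param t numeric vector of times (s) from stimulus onset.
#' @return Bar-center position in degrees; NA during the inter-sweep gap.
#' @export
barPosition <- function(traj, t) {
  tau <- t %% traj@periodS
  pos <- traj@startDeg + traj@speedDegPerS * tau
  pos[tau > traj@sweepDurationS] <- NA_real_
  pos
}

## Inverse of barPosition: time within the period at which the bar center
## crosses a given position.
barCrossingTime <- function(traj, posDeg) {
  tt <- (posDeg - traj@startDeg) / traj@speedDegPerS
  tt[tt < 0 | tt > traj@sweepDurationS] <- NA_real_
  tt
}

#' Render drifting-checkerboard frames in visual coordinates
#'
#' Frames are rendered on a regular visual-degree grid (default one degree
#' per pixel), not on monitor pixels: each frame is background luminance
#' everywhere except within the bar, which is filled with a checkerboard of
#' \code{squareSizeDeg} squares counterphasing at the flicker rate.
#'
#' @param spec a \linkS4class{CheckerboardSpec}.
#' @param geom a \linkS4class{MonitorGeometry}.
#' @param direction sweep direction, see \code{\link{barTrajectory}}.
#' @param times numeric vector of frame times (s), monotone increasing.
#' @param resolutionDeg visual-degree grid step.
#' @return A list with \code{frames} (time x rows x cols luminance array in
#'   [0, 1]; rows = altitude descending, cols = azimuth ascending),
#'   \code{trajectory} (\linkS4class{BarTrajectory}), and
#'   \code{barCenterDeg} (bar position per frame).
#' @export
checkerboardFrames <- function(spec = CheckerboardSpec(),
                               geom = MonitorGeometry(),
                               direction = "N2T", times = seq(0, 1, 0.1),
                               resolutionDeg = 1) {
  stopIfNot(all(diff(times) > 0), "times must be monotone increasing")
  traj <- barTrajectory(spec, geom, direction)
  azi <- seq(geom@azimuthExtentDeg[1] + resolutionDeg / 2,
             geom@azimuthExtentDeg[2], by = resolutionDeg)
  alt <- seq(geom@altitudeExtentDeg[2] - resolutionDeg / 2,
             geom@altitudeExtentDeg[1], by = -resolutionDeg)
  along <- if (traj@axis == "azimuth") matrix(azi, length(alt), length(azi),
                                              byrow = TRUE)
           else matrix(alt, length(alt), length(azi))
  perp <- if (traj@axis == "azimuth") matrix(alt, length(alt), length(azi))
          else matrix(azi, length(alt), length(azi), byrow = TRUE)
  checker <- (floor(along / spec@squareSizeDeg) +
                floor(perp / spec@squareSizeDeg)) %% 2
  frames <- array(spec@backgroundLuminance,
                  dim = c(length(times), length(alt), length(azi)))
  centers <- barPosition(traj, times)
  for (i in seq_along(times)) {
    if (is.na(centers[i])) next
    inBar <- abs(along - centers[i]) < spec@barWidthDeg / 2
    phase <- floor(2 * spec@flickerHz * times[i]) %% 2
    pat <- (checker + phase) %% 2
    f <- frames[i, , ]
    f[inBar] <- pat[inBar]
    frames[i, , ] <- f
  }
  list(frames = frames, trajectory = traj, barCenterDeg = centers)
}

#' Pseudorandom sparse-noise event sequence
#'
#' Every grid location appears exactly \code{repeatsPerPolarity} times per
#' polarity, in a seeded pseudorandom order; the global RNG stream is left
#' untouched.
#'
#' @param spec a \linkS4class{SparseNoiseSpec}.
#' @param seed integer seed; the sequence is reproducible for a fixed seed.
#' @return A data.frame with one row per event: \code{onsetS}, \code{row},
#'   \code{col} (grid indices), \code{altitudeDeg}, \code{azimuthDeg}
#'   (square centers), \code{polarity} (-1 black, +1 white).
#' @export
sparseNoiseEvents <- function(spec = SparseNoiseSpec(), seed = 1L) {
  e <- spec@gridExtentDeg
  aziC <- seq(e[1] + spec@squareSizeDeg / 2, e[2], by = spec@squareSizeDeg)
  altC <- seq(e[3] + spec@squareSizeDeg / 2, e[4], by = spec@squareSizeDeg)
  base <- expand.grid(row = seq_along(altC), col = seq_along(aziC),
                      polarity = c(-1L, 1L))
  events <- base[rep(seq_len(nrow(base)), spec@repeatsPerPolarity), ]
  ord <- withLocalSeed(seed, sample.int(nrow(events)))
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL
  events$altitudeDeg <- altC[events$row]
  events$azimuthDeg <- aziC[events$col]
  events$onsetS <- (seq_len(nrow(events)) - 1) * spec@durationS
  events[, c("onsetS", "row", "col", "altitudeDeg", "azimuthDeg", "polarity")]
}
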
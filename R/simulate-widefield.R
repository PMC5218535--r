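#' @include AllClasses.R utils.R stimulus.R atlas.R
NULL

#' Linear photobleaching rate under constant illumination
#'
#' Fluorescence declines approximately linearly with cumulative light dose;
#' scaling the bleaching coefficient (percent lost per J/mm^2) by the
#' illumination intensity gives the decline rate in percent per second and
#' per minute.
#'
#' @param coeffPctPerJmm2 bleaching coefficient (percent per J/mm^2;
#'   default 235).
#' @param illuminationUwPerMm2 illumination intensity (uW/mm^2; default 89).
#' @return A list with \code{percentPerSecond} and \code{percentPerMinute}.
#' @examples
#' photobleachRate()   # ~0.02 %/s, ~1.25 %/min
#' @export
photobleachRate <- function(coeffPctPerJmm2 = 235,
                            illuminationUwPerMm2 = 89) {
  perS <- coeffPctPerJmm2 * illuminationUwPerMm2 * 1e-6
  list(percentPerSecond = perS, percentPerMinute = perS * 60)
}

## Crossing response kernel: boxcar (bar occupancy of the preferred
## position) convolved with a difference-of-exponentials calcium kernel,
## normalized to unit peak.  Returned as a lookup table.
crossingKernel <- function(spec, config) {
  w <- spec@barWidthDeg / spec@sweepSpeedDegPerS
  dt <- 0.02
  tau <- seq(-w / 2 - 0.2, w / 2 + 6 * config@decayS, by = dt)
  h <- exp(-pmax(tau, 0) / config@decayS) - exp(-pmax(tau, 0) / config@riseS)
  h[tau < 0] <- 0
  box <- as.numeric(abs(tau) <= w / 2)
  k <- stats::convolve(box, rev(h), type = "open")
  ## align: convolution output sample i corresponds to lag tau[1]*2 + (i-1)*dt
  kt <- seq(2 * tau[1], by = dt, length.out = length(k))
  keep <- kt >= tau[1] & kt <= max(tau) + w / 2
  k <- k[keep]; kt <- kt[keep]
  k <- k / max(k)
  list(tau = kt, k = k)
}

#' Simulate a widefield sweep movie from a ground-truth atlas
#'
#' Forward model of periodic-stimulus acquisition: each cortical pixel's
#' fluorescence is baseline x (1 - bleach rate x t) x (1 + amplitude x
#' response) + noise, where the response is the crossing kernel (bar
#' occupancy convolved with the calcium kernel) centered on the time the bar
#' crosses the pixel's ground-truth preferred position.  Pixels outside all
#' areas, or whose preferred position lies outside the sweep extent, carry a
#' baseline-only trace.  Trials share the ground truth and differ only in
#' noise.
#'
#' @param atlas a \linkS4class{CorticalAtlas}.
#' @param direction sweep direction ("N2T", "T2N", "D2U", "U2D").
#' @param spec a \linkS4class{CheckerboardSpec}.
#' @param geom a \linkS4class{MonitorGeometry}.
#' @param config a \linkS4class{SimulationConfig}; \code{nCycles} repetition
#'   periods are simulated after \code{baselineWindowS} of pre-stimulus
#'   baseline.
#' @param nTrials number of trials.
#' @param baselineF baseline fluorescence in camera units.
#' @return A \linkS4class{Movie} (kind "raw").
#' @export
simulateSweepMovie <- function(atlas, direction = "N2T",
                               spec = CheckerboardSpec(),
                               geom = MonitorGeometry(),
                               config = SimulationConfig(), nTrials = 1,
                               baselineF = 100) {
  traj <- barTrajectory(spec, geom, direction)
  gt <- atlasPositionMaps(atlas)
  pos <- if (traj@axis == "azimuth") azimuth(gt) else altitude(gt)
  amp <- amplitudeMap(gt)
  fr <- config@frameRateHz
  ## a small margin guarantees nCycles complete periods after onset
  nFrames <- ceiling((config@baselineWindowS +
                        config@nCycles * traj@periodS) * fr) + 2
  t <- (seq_len(nFrames) - 1) / fr
  onset <- config@baselineWindowS
  tc <- barCrossingTime(traj, as.vector(pos))  # NA outside extent / areas
  kern <- crossingKernel(spec, config)
  npx <- length(pos)
  resp <- matrix(0, nFrames, npx)
  act <- which(!is.na(tc) & as.vector(amp) > 0)
  if (length(act)) {
    tRel <- t - onset
    tau <- outer(tRel, tc[act], "-")
    tau <- ((tau + traj@periodS / 2) %% traj@periodS) - traj@periodS / 2
    v <- stats::approx(kern$tau, kern$k, xout = as.vector(tau),
                       yleft = 0, yright = 0, rule = 1)$y
    v[is.na(v)] <- 0
    v <- matrix(v, nFrames, length(act))
    v[tRel < 0, ] <- 0   # stimulus not yet on
    resp[, act] <- v * rep(as.vector(amp)[act], each = nFrames)
  }
  bleach <- photobleachRate(config@photobleachCoeff,
                            config@illumination)$percentPerSecond / 100
  base <- baselineF * (1 - bleach * t)
  frame1 <- base * (1 + config@responseAmplitude * resp)  # nFrames x npx
  data <- array(0, dim = c(nTrials, nFrames, atlas@dims[1], atlas@dims[2]))
  noise <- config@noiseSd * baselineF
  withLocalSeed(config@seed + match(direction, c("N2T", "T2N", "D2U", "U2D")),
    for (tr in seq_len(nTrials)) {
      x <- frame1
      if (noise > 0) x <- x + matrix(stats::rnorm(length(x), sd = noise),
                                     nrow(x), ncol(x))
      data[tr, , , ] <- array(x, dim = c(nFrames, atlas@dims[1],
                                         atlas@dims[2]))
    })
  data[data < 0] <- 0
  new("Movie", data = data, frameRate = fr, direction = direction,
      onsetS = onset, trajectory = traj, kind = "raw",
      pixelSizeUm = atlas@pixelSizeUm)
}

#' Simulate the standard four-direction mapping session
#'
#' @param atlas a \linkS4class{CorticalAtlas}.
#' @param nTrials trials per direction.
#' @param ... passed to \code{\link{simulateSweepMovie}}.
#' @return A named list of four \linkS4class{Movie}s
#'   (N2T, T2N, D2U, U2D).
#' @export
simulateMappingSession <- function(atlas, nTrials = 1, ...) {
  dirs <- c("N2T", "T2N", "D2U", "U2D")
  out <- lapply(dirs, function(d)
    simulateSweepMovie(atlas, direction = d, nTrials = nTrials, ...))
  names(out) <- dirs
  out
}
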
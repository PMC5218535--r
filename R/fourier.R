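#' @include AllClasses.R utils.R stimulus.R
NULL

#' Spectral bands of the stimulus first harmonic
#'
#' Peak frequencies and analysis bands matching the stimulus repetition
#' rates: 0.043 Hz (0.022-0.065 Hz band) for azimuth and 0.048 Hz
#' (0.024-0.072 Hz band) for altitude maps.
#'
#' @return A list with elements \code{azimuth} and \code{altitude}, each a
#'   list with \code{center} (Hz) and \code{band} (Hz pair).
#' @export
harmonicBands <- function() {
  list(azimuth = list(center = 0.043, band = c(0.022, 0.065)),
       altitude = list(center = 0.048, band = c(0.024, 0.072)))
}

#' Delta-F movie: subtract the pre-stimulus mean image
#'
#' For each trial, subtracts from every frame the mean of the
#' \code{baselineWindowS} seconds preceding stimulus onset.
#'
#' @param movie a raw \linkS4class{Movie} with at least
#'   \code{baselineWindowS} of pre-stimulus frames.
#' @param baselineWindowS baseline duration (s; default 2).
#' @return A \linkS4class{Movie} of kind "deltaF".
#' @export
computeDeltaF <- function(movie, baselineWindowS = 2) {
  fr <- movie@frameRate
  onsetFrame <- round(movie@onsetS * fr)
  nBase <- round(baselineWindowS * fr)
  if (onsetFrame < nBase)
    stop("insufficient pre-stimulus frames for a ", baselineWindowS,
         " s baseline")
  d <- movie@data
  baseIdx <- (onsetFrame - nBase + 1):onsetFrame
  for (tr in seq_len(dim(d)[1])) {
    x <- array(d[tr, , , ], dim(d)[2:4])
    baseImg <- colMeans(x[baseIdx, , , drop = FALSE], dims = 1)
    d[tr, , , ] <- sweep(x, c(2, 3), baseImg, "-")
  }
  methods::initialize(movie, data = d, kind = "deltaF")
}

#' Trial-averaged movie
#'
#' @param movie a \linkS4class{Movie}.
#' @return The same movie with a single trial holding the mean over trials.
#' @export
trialMean <- function(movie) {
  m <- colMeans(movie@data, dims = 1)
  methods::initialize(movie, data = array(m, dim = c(1, dim(m))))
}

## Mean delta-F frames (time x rows x cols) of a movie, computing delta F
## first when given raw data.
meanDeltaF <- function(movie, baselineWindowS = 2) {
  if (movie@kind == "raw") movie <- computeDeltaF(movie, baselineWindowS)
  colMeans(movie@data, dims = 1)
}

## First-harmonic phase analysis of one direction movie.  Returns per-pixel
## peak time within the stimulus period and in-band amplitude.
directionPhase <- function(movie, band, detrend = TRUE,
                           baselineWindowS = 2) {
  fr <- movie@frameRate
  traj <- movie@trajectory
  dff <- meanDeltaF(movie, baselineWindowS)
  nFrames <- dim(dff)[1]
  onsetFrame <- round(movie@onsetS * fr)
  perFrames <- traj@periodS * fr
  nCyc <- floor((nFrames - onsetFrame) / perFrames)
  stopIfNot(nCyc >= 1, "movie shorter than one stimulus period")
  nUse <- round(nCyc * perFrames)
  seg <- dff[onsetFrame + seq_len(nUse), , , drop = FALSE]
  npx <- prod(dim(seg)[2:3])
  y <- matrix(seg, nUse, npx)
  tt <- (seq_len(nUse) - 1) / fr
  if (detrend) {
    D <- cbind(1, tt)
    yd <- y - D %*% solve(crossprod(D), crossprod(D, y))
  } else yd <- y
  z <- stats::mvfft(yd)
  freqs <- (seq_len(nUse) - 1) * fr / nUse
  bandIdx <- which(freqs >= band$band[1] & freqs <= band$band[2] & freqs > 0)
  stopIfNot(length(bandIdx) >= 1, "no DFT bin falls inside the band")
  mag <- Mod(z[bandIdx, , drop = FALSE])
  best <- bandIdx[max.col(t(mag), ties.method = "first")]
  ## phase and amplitude from a joint least-squares fit of trend + harmonic
  ## at the selected bin frequency, which keeps the linear photobleaching
  ## trend from leaking into the harmonic phase
  amp <- numeric(npx); phase <- numeric(npx)
  for (k in unique(best)) {
    px <- which(best == k)
    w <- 2 * pi * freqs[k]
    X <- if (detrend) cbind(1, tt, cos(w * tt), sin(w * tt)) else
      cbind(1, cos(w * tt), sin(w * tt))
    beta <- solve(crossprod(X), crossprod(X, y[, px, drop = FALSE]))
    nb <- nrow(beta)
    amp[px] <- sqrt(beta[nb - 1, ]^2 + beta[nb, ]^2)
    phase[px] <- atan2(-beta[nb, ], beta[nb - 1, ])
  }
  f <- freqs[best]
  tPeak <- ((-phase / (2 * pi)) %% 1) / f
  pos <- traj@startDeg + traj@speedDegPerS * tPeak
  ## peak times that fall in the inter-sweep gap have no bar position
  pos[tPeak > traj@sweepDurationS + 0.5 / fr] <- NA_real_
  dimShape <- dim(seg)[2:3]
  list(position = matrix(pos, dimShape[1], dimShape[2]),
       amplitude = matrix(amp, dimShape[1], dimShape[2]),
       axis = traj@axis)
}

#' Extract altitude/azimuth position maps from direction movies
#'
#' Per pixel, the phase of the first harmonic at the in-band peak frequency
#' is converted to a bar-center position through the linear trajectory;
#' position estimates from stimuli travelling in opposite directions are
#' then averaged pixel-by-pixel, cancelling the common response delay.
#' Altitude comes from the vertical pair (D2U/U2D), azimuth from the
#' horizontal pair (N2T/T2N); a single direction of a pair is used alone
#' (without delay cancellation) when its partner is absent.
#'
#' @param movies list of \linkS4class{Movie}s (raw or deltaF), any subset of
#'   the four directions; named by direction or carrying their own
#'   \code{direction} slot.
#' @param bands harmonic bands, as \code{\link{harmonicBands}}.
#' @param detrend remove a per-pixel linear trend (photobleaching) before
#'   the Fourier analysis.
#' @param minAmplitudeFrac validity floor: pixels whose in-band amplitude is
#'   below this fraction of the maximum amplitude are flagged invalid.
#' @param baselineWindowS baseline window for delta-F conversion (s).
#' @return A \linkS4class{PositionMaps}.
#' @export
extractPositionMaps <- function(movies, bands = harmonicBands(),
                                detrend = TRUE, minAmplitudeFrac = 0.2,
                                baselineWindowS = 2) {
  if (methods::is(movies, "Movie")) movies <- list(movies)
  dirs <- vapply(movies, function(m) m@direction, character(1))
  names(movies) <- dirs
  stopIfNot(length(unique(dirs)) == length(dirs),
            "duplicate stimulus directions")
  res <- lapply(movies, function(m) {
    band <- if (m@trajectory@axis == "azimuth") bands$azimuth else
      bands$altitude
    directionPhase(m, band, detrend = detrend,
                   baselineWindowS = baselineWindowS)
  })
  pairAvg <- function(nms) {
    have <- intersect(nms, names(res))
    if (!length(have)) return(NULL)
    pos <- Reduce("+", lapply(have, function(n) res[[n]]$position)) /
      length(have)
    amp <- Reduce("+", lapply(have, function(n) res[[n]]$amplitude)) /
      length(have)
    list(position = pos, amplitude = amp)
  }
  az <- pairAvg(c("N2T", "T2N"))
  al <- pairAvg(c("D2U", "U2D"))
  stopIfNot(!is.null(az) || !is.null(al),
            "no usable direction movies supplied")
  shape <- dim(res[[1]]$position)
  naMat <- matrix(NA_real_, shape[1], shape[2])
  amp <- if (!is.null(az) && !is.null(al))
    (az$amplitude + al$amplitude) / 2
  else if (!is.null(az)) az$amplitude else al$amplitude
  valid <- amp >= minAmplitudeFrac * max(amp)
  if (!is.null(az)) valid <- valid & is.finite(az$position)
  if (!is.null(al)) valid <- valid & is.finite(al$position)
  alt <- if (is.null(al)) naMat else al$position
  azi <- if (is.null(az)) naMat else az$position
  alt[!valid] <- NA_real_
  azi[!valid] <- NA_real_
  PositionMaps(altitude = alt, azimuth = azi, amplitude = amp, valid = valid,
               pixelSizeUm = movies[[1]]@pixelSizeUm)
}

#' Normalized in-band spectral power map
#'
#' Per-pixel spectral power within the harmonic band of a delta-F/F movie,
#' normalized to the mean power inside a reference (V1) region.
#'
#' @param movie a \linkS4class{Movie}.
#' @param band list with \code{band} (Hz pair), e.g. an element of
#'   \code{\link{harmonicBands}}.
#' @param referenceMask logical matrix marking the reference region.
#' @param detrend,baselineWindowS as in \code{\link{extractPositionMaps}}.
#' @return A numeric matrix; the reference region has mean 1.
#' @export
powerMap <- function(movie, band = harmonicBands()$azimuth, referenceMask,
                     detrend = TRUE, baselineWindowS = 2) {
  fr <- movie@frameRate
  dff <- meanDeltaF(movie, baselineWindowS)
  onsetFrame <- round(movie@onsetS * fr)
  nUse <- dim(dff)[1] - onsetFrame
  y <- matrix(dff[onsetFrame + seq_len(nUse), , , drop = FALSE], nUse)
  if (detrend) {
    D <- cbind(1, seq_len(nUse))
    y <- y - D %*% solve(crossprod(D), crossprod(D, y))
  }
  z <- stats::mvfft(y)
  freqs <- (seq_len(nUse) - 1) * fr / nUse
  idx <- which(freqs >= band$band[1] & freqs <= band$band[2] & freqs > 0)
  p <- colSums(Mod(z[idx, , drop = FALSE])^2)
  p <- matrix(p, dim(dff)[2], dim(dff)[3])
  stopIfNot(identical(dim(referenceMask), dim(p)),
            "reference mask shape mismatch")
  ref <- mean(p[referenceMask])
  stopIfNot(is.finite(ref) && ref > 0, "reference region has zero power")
  p / ref
}

#' Response metrics for a brief stimulus
#'
#' The trial-averaged movie is converted to delta F/F against the 2 s
#' pre-stimulus baseline; each frame is Gaussian filtered (sigma 258 um) and
#' a 516 um square region of interest is centered on the extremum pixel of
#' the maximum-intensity projection (minimum for negative-going responses).
#' Metrics are computed on the ROI-mean trace; time to peak is measured from
#' stimulus onset and rise/decay times between 10 and 90 percent of peak by
#' linear interpolation.
#'
#' @param movie a raw \linkS4class{Movie} (trials x time x rows x cols).
#' @param onsetS stimulus onset (s); must lie inside the movie.
#' @param pixelSizeUm pixel size; defaults to the movie's own.
#' @param filterSigmaUm spatial filter sigma (um).
#' @param roiUm ROI side length (um).
#' @param baselineWindowS baseline window (s).
#' @return A list: \code{metrics} (peakDff, timeToPeakS, rise1090S,
#'   decay1090S), \code{trace} (ROI-mean delta F/F), \code{timeS},
#'   \code{roiCenter} (row, col).
#' @export
briefStimMetrics <- function(movie, onsetS = movie@onsetS,
                             pixelSizeUm = movie@pixelSizeUm,
                             filterSigmaUm = 258, roiUm = 516,
                             baselineWindowS = 2) {
  fr <- movie@frameRate
  d <- apply(movie@data, c(2, 3, 4), mean)
  nFrames <- dim(d)[1]
  onsetFrame <- round(onsetS * fr)
  stopIfNot(onsetFrame >= 1 && onsetFrame < nFrames,
            "stimulus onset lies outside the movie")
  nBase <- min(round(baselineWindowS * fr), onsetFrame)
  fRest <- apply(d[(onsetFrame - nBase + 1):onsetFrame, , , drop = FALSE],
                 c(2, 3), mean)
  stopIfNot(all(fRest > 0), "resting fluorescence must be positive")
  dff <- sweep(sweep(d, c(2, 3), fRest, "-"), c(2, 3), fRest, "/")
  sigmaPx <- filterSigmaUm / pixelSizeUm
  sm <- array(0, dim(dff))
  for (i in seq_len(nFrames)) sm[i, , ] <- gaussianBlur(dff[i, , ], sigmaPx)
  post <- sm[(onsetFrame + 1):nFrames, , , drop = FALSE]
  mx <- apply(post, c(2, 3), max)
  mn <- apply(post, c(2, 3), min)
  negative <- max(abs(mn)) > max(abs(mx))
  proj <- if (negative) mn else mx
  ctr <- which(if (negative) proj == min(proj) else proj == max(proj),
               arr.ind = TRUE)[1, ]
  half <- max(1, round(roiUm / pixelSizeUm / 2))
  rows <- max(1, ctr[1] - half + 1):min(dim(dff)[2], ctr[1] + half)
  cols <- max(1, ctr[2] - half + 1):min(dim(dff)[3], ctr[2] + half)
  trace <- apply(dff[, rows, cols, drop = FALSE], 1, mean)
  timeS <- (seq_len(nFrames) - 1) / fr
  post <- trace[(onsetFrame + 1):nFrames]
  sgn <- if (negative) -1 else 1
  ipk <- which.max(sgn * post)
  peak <- post[ipk]
  tPk <- ipk / fr
  crossing <- function(x, tx, level, rising = TRUE) {
    ## first time x crosses `level` (in the direction given), interpolated
    above <- if (rising) x >= level else x <= level
    i <- which(above)[1]
    if (is.na(i) || i == 1) return(tx[ifelse(is.na(i), length(tx), 1)])
    frac <- (level - x[i - 1]) / (x[i] - x[i - 1])
    tx[i - 1] + frac * (tx[i] - tx[i - 1])
  }
  tPost <- seq_along(post) / fr
  up <- sgn * post
  pk <- sgn * peak
  t10 <- crossing(up[1:ipk], tPost[1:ipk], 0.1 * pk)
  t90 <- crossing(up[1:ipk], tPost[1:ipk], 0.9 * pk)
  dec <- up[ipk:length(up)]
  tDec <- tPost[ipk:length(up)]
  d90 <- crossing(dec, tDec, 0.9 * pk, rising = FALSE)
  d10 <- crossing(dec, tDec, 0.1 * pk, rising = FALSE)
  list(metrics = list(peakDff = peak, timeToPeakS = tPk,
                      rise1090S = t90 - t10, decay1090S = d10 - d90),
       trace = trace, timeS = timeS, roiCenter = unname(ctr))
}
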
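## A minimal single-pixel movie pair along one axis, with the response a
## pure peaked waveform at the stimulus frequency.
tinyMoviePair <- function(posDeg, delayS = 0, scale = 1, frameRate = 10,
                          nCycles = 3) {
  spec <- CheckerboardSpec()
  geom <- MonitorGeometry()
  lapply(c("D2U", "U2D"), function(d) {
    traj <- barTrajectory(spec, geom, d)
    nFrames <- ceiling((2 + nCycles * traj@periodS) * frameRate) + 2
    t <- (seq_len(nFrames) - 1) / frameRate
    tc <- (posDeg - traj@startDeg) / traj@speedDegPerS + delayS
    tau <- ((t - 2 - tc + traj@periodS / 2) %% traj@periodS) -
      traj@periodS / 2
    resp <- scale * exp(-tau^2 / (2 * 0.8^2))
    resp[t < 2] <- 0
    arr <- array(100 * (1 + 0.1 * resp), c(1, nFrames, 1, 1))
    new("Movie", data = arr, frameRate = frameRate, direction = d,
        onsetS = 2, trajectory = traj, kind = "raw", pixelSizeUm = 25)
  })
}

test_that("delta-F subtracts the pre-stimulus mean image", {
  traj <- barTrajectory(direction = "N2T")
  const <- new("Movie", data = array(7, c(2, 50, 3, 3)), frameRate = 10,
               direction = "N2T", onsetS = 2, trajectory = traj,
               kind = "raw", pixelSizeUm = NA_real_)
  expect_true(all(computeDeltaF(const)@data == 0))
  ## step of +k after onset
  d <- array(5, c(1, 50, 2, 2)); d[, 21:50, , ] <- 5 + 3
  step <- methods::initialize(const, data = d)
  df <- computeDeltaF(step)@data
  expect_true(all(df[, 1:20, , ] == 0))
  expect_true(all(df[, 21:50, , ] == 3))
  ## random movie: baseline-window mean of delta F is zero per pixel
  set.seed(3)
  rnd <- methods::initialize(const,
    data = array(runif(2 * 50 * 9, 1, 2), c(2, 50, 3, 3)))
  dfr <- computeDeltaF(rnd)@data
  baseMeans <- apply(dfr[, 1:20, , , drop = FALSE], c(1, 3, 4), mean)
  expect_lt(max(abs(baseMeans)), 1e-12)
  ## too little pre-stimulus data
  early <- methods::initialize(const, onsetS = 0.5)
  expect_error(computeDeltaF(early), "pre-stimulus")
})

test_that("a zero-delay sinusoidal pixel maps back to its position", {
  mov <- tinyMoviePair(posDeg = 12)
  maps <- extractPositionMaps(mov, minAmplitudeFrac = 0)
  expect_equal(altitude(maps)[1, 1], 12, tolerance = 0.05)
})

test_that("a common response delay cancels between opposite directions", {
  del <- 0.8
  single <- extractPositionMaps(tinyMoviePair(5, delayS = del)[1],
                                minAmplitudeFrac = 0)
  expect_equal(altitude(single)[1, 1], 5 + 9 * del, tolerance = 0.1)
  both <- extractPositionMaps(tinyMoviePair(5, delayS = del),
                              minAmplitudeFrac = 0)
  expect_equal(altitude(both)[1, 1], 5, tolerance = 0.02)
})

test_that("scaling delta F scales amplitude linearly, positions unchanged", {
  m1 <- extractPositionMaps(tinyMoviePair(8, scale = 1),
                            minAmplitudeFrac = 0)
  m3 <- extractPositionMaps(tinyMoviePair(8, scale = 3),
                            minAmplitudeFrac = 0)
  expect_equal(amplitudeMap(m3)[1, 1] / amplitudeMap(m1)[1, 1], 3,
               tolerance = 1e-6)
  expect_equal(altitude(m3)[1, 1], altitude(m1)[1, 1], tolerance = 1e-9)
})

test_that("noise-free simulation recovers the atlas positions within 1 degree", {
  gt <- fxGtMaps()
  maps <- fxRecoveredMaps()
  v <- validMask(maps) & validMask(gt)
  expect_gt(sum(v), 0.95 * sum(validMask(gt)))
  expect_lt(sqrt(mean((altitude(maps)[v] - altitude(gt)[v])^2)), 1)
  expect_lt(sqrt(mean((azimuth(maps)[v] - azimuth(gt)[v])^2)), 1)
})

test_that("trial averaging reduces position noise roughly as 1/sqrt(N)", {
  atlas <- fxSmallAtlas()
  gt <- atlasPositionMaps(atlas)
  sdAt <- function(n, noiseSd = 0.02) {
    cfg <- SimulationConfig(noiseSd = noiseSd, nCycles = 2, seed = 11)
    mov <- simulateMappingSession(atlas, nTrials = n, config = cfg)
    maps <- extractPositionMaps(mov)
    v <- validMask(maps) & validMask(gt)
    sqrt(mean((azimuth(maps)[v] - azimuth(gt)[v])^2))
  }
  s0 <- sdAt(1, noiseSd = 0)              # systematic (noise-free) floor
  s <- vapply(c(1, 4, 16), sdAt, numeric(1))
  expect_true(all(diff(s) < 0))           # monotone improvement
  ## after removing the systematic floor, each 4x trial increase shrinks
  ## the noise part of the error by about half
  sNet <- sqrt(pmax(s^2 - s0^2, 0))
  expect_equal(sNet[2] / sNet[1], 0.5, tolerance = 0.25)
  expect_equal(sNet[3] / sNet[2], 0.5, tolerance = 0.3)
})

test_that("power maps normalize to the reference region", {
  atlas <- fxSmallAtlas()
  mov <- fxSmallPowerMovie <- simulateSweepMovie(
    atlas, "N2T", config = SimulationConfig(noiseSd = 0, nCycles = 2))
  ref <- atlas@areas$V1$mask
  p <- powerMap(mov, harmonicBands()$azimuth, ref)
  expect_equal(mean(p[ref]), 1, tolerance = 1e-9)
  expect_error(powerMap(mov, harmonicBands()$azimuth,
                        matrix(FALSE, 24, 24) | (labelImage(atlas) == 99)))
  ## doubling the response amplitude quadruples unnormalized power:
  ## measured here as the ratio between areas of amplitude 2 and 1
  atlas2 <- buildDefaultAtlas(amplitudes = c(LM = 2))
  mov2 <- simulateSweepMovie(atlas2, "N2T",
    config = SimulationConfig(noiseSd = 0, nCycles = 2))
  p2 <- powerMap(mov2, harmonicBands()$azimuth, atlas2@areas$V1$mask)
  lmOverV1 <- mean(p2[atlas2@areas$LM$mask])
  expect_equal(lmOverV1, 4, tolerance = 0.15)
})

test_that("brief-stimulus metrics match closed forms", {
  ## build a 20 x 20 movie with a Gaussian spatial blob whose ROI trace
  ## rises linearly 0 -> 1 over 1 s then decays linearly over 2 s
  fr <- 50
  nFrames <- 6 * fr
  onset <- 2
  t <- (seq_len(nFrames) - 1) / fr
  shape <- ifelse(t < onset, 0,
                  ifelse(t < onset + 1, t - onset,
                         pmax(0, 1 - (t - onset - 1) / 2)))
  rows <- matrix(1:20, 20, 20); cols <- t(rows)
  blob <- exp(-((rows - 10)^2 + (cols - 10)^2) / (2 * 3^2))
  arr <- array(0, c(1, nFrames, 20, 20))
  for (i in seq_len(nFrames))
    arr[1, i, , ] <- 100 * (1 + 0.2 * shape[i] * blob)
  mov <- new("Movie", data = arr, frameRate = fr, direction = "N2T",
             onsetS = onset, trajectory = barTrajectory(direction = "N2T"),
             kind = "raw", pixelSizeUm = 51.6)
  res <- briefStimMetrics(mov)
  expect_equal(res$roiCenter, c(10, 10), tolerance = 1)
  expect_equal(res$metrics$timeToPeakS, 1, tolerance = 1.5 / fr)
  expect_equal(res$metrics$rise1090S, 0.8, tolerance = 2 / fr)
  expect_equal(res$metrics$decay1090S, 1.6, tolerance = 2 / fr)
  ## peak timing example: transient peaking 0.25 s after onset
  arr2 <- arr
  shape2 <- pmax(0, 1 - abs(t - onset - 0.25) / 0.25)
  for (i in seq_len(nFrames))
    arr2[1, i, , ] <- 100 * (1 + 0.2 * shape2[i] * blob)
  res2 <- briefStimMetrics(methods::initialize(mov, data = arr2))
  expect_lt(abs(res2$metrics$timeToPeakS - 0.25), 1.5 / fr)
  expect_error(briefStimMetrics(mov, onsetS = 99), "outside")
})
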
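circleMask <- function(n, ctr, r) {
  rows <- matrix(seq_len(n), n, n); cols <- t(rows)
  (rows - ctr[1])^2 + (cols - ctr[2])^2 <= r^2
}

test_that("neuropil annuli are dilation bands excluding all somata", {
  n <- 120
  soma <- circleMask(n, c(60, 60), 5)    # area ~78 px ~153 um^2 at 1.4 um
  rs <- buildNeuropilMasks(list(soma))
  ann <- rs$neuropil[[1]]
  expect_false(any(ann & soma))
  ## area close to pi ((r+15)^2 - (r+5)^2) for an isolated disk
  want <- pi * (20^2 - 10^2)
  expect_equal(sum(ann), want, tolerance = 0.1)
  ## two abutting somata exclude each other's pixels
  s1 <- circleMask(n, c(40, 40), 5); s2 <- circleMask(n, c(40, 52), 5)
  rs2 <- buildNeuropilMasks(list(s1, s2))
  expect_false(any(rs2$neuropil[[1]] & s2))
  expect_false(any(rs2$neuropil[[2]] & s1))
  ## a 50 um^2 soma (under the 59 um^2 floor) is filtered out
  tiny <- circleMask(n, c(100, 100), 2.8)   # ~25 px ~ 50 um^2
  rs3 <- buildNeuropilMasks(list(soma, tiny))
  expect_identical(rs3$keptIds, 1L)
  big <- circleMask(n, c(60, 60), 15)       # ~707 px ~ 1385 um^2
  expect_error(buildNeuropilMasks(list(big)), "size filter")
})

test_that("the contamination ratio is recovered across injected values", {
  for (rT in c(0.1, 0.244, 0.5)) {
    ses <- simulateTwoPhotonSession(nCells = 4, rTrue = rT, seed = 7,
      spec = SparseNoiseSpec(repeatsPerPolarity = 10))
    for (i in 1:4) {
      fit <- estimateNeuropilRatio(ses$measured[, i], ses$neuropil[, i])
      expect_lt(abs(fit$r - rT), 0.02,
                label = paste("r error at injected", rT))
    }
  }
  ## contamination 0 against an uncorrelated noise regressor
  set.seed(2)
  fm <- 1 + as.numeric(stats::filter(rnorm(3000, sd = 0.05), 0.9,
                                     method = "recursive"))
  fn <- rnorm(3000)
  expect_lt(estimateNeuropilRatio(fm, fn)$r, 0.02)
  ## degenerate neuropil: r = 0 with a warning
  expect_warning(out <- estimateNeuropilRatio(fm, rep(1, 3000)),
                 "degenerate")
  expect_equal(out$r, 0)
})

test_that("receptive-field maps localize the injected field", {
  ses <- fxTwoPhoton()
  i <- 1
  fit <- estimateNeuropilRatio(ses$measured[, i], ses$neuropil[, i])
  rf <- computeRfMaps(fit$corrected, ses$events, ses$frameRate)
  expect_true(rf@responsive)
  ## the raw On map correlates with the injected Gaussian profile
  want <- exp(-(outer((rf@gridAltDeg - ses$cells$rfAltDeg[i])^2,
                      (rf@gridAziDeg - ses$cells$rfAziDeg[i])^2, "+")) /
                (2 * ses$spec@squareSizeDeg^2))
  expect_gt(stats::cor(as.vector(rf@on), as.vector(want)), 0.9)
  ctr <- rfCenter(rf)
  expect_lt(abs(ctr["altitude"] - ses$cells$rfAltDeg[i]), 3)
  expect_lt(abs(ctr["azimuth"] - ses$cells$rfAziDeg[i]), 3)
})

test_that("a trace driven by one location yields a delta-like On map", {
  spec <- SparseNoiseSpec(squareSizeDeg = 6, repeatsPerPolarity = 4,
                          gridExtentDeg = c(0, 30, 0, 30))
  ev <- sparseNoiseEvents(spec, seed = 3)
  fr <- 30
  nFrames <- ceiling((max(ev$onsetS) + 2) * fr)
  trace <- rep(1, nFrames)
  hit <- ev$row == 2 & ev$col == 3 & ev$polarity == 1
  for (on in round(ev$onsetS[hit] * fr) + 1)
    trace[on:(on + 5)] <- trace[on:(on + 5)] + 1
  rf <- computeRfMaps(trace, ev, fr)
  expect_equal(unname(which(rf@on == max(rf@on), arr.ind = TRUE)[1, ]),
               c(2, 3))
  zPeak <- which(rf@zOn == max(rf@zOn), arr.ind = TRUE)[1, ]
  expect_equal(unname(rf@upAltDeg[zPeak[1]]), unname(rf@gridAltDeg[2]),
               tolerance = 4)
})

test_that("noise-only traces are rarely responsive, as the z threshold implies", {
  spec <- SparseNoiseSpec(repeatsPerPolarity = 2)
  ev <- sparseNoiseEvents(spec, seed = 4)
  fr <- 30
  nFrames <- ceiling((max(ev$onsetS) + 2) * fr)
  set.seed(10)
  hits <- replicate(40, {
    rf <- computeRfMaps(1 + rnorm(nFrames, sd = 0.05), ev, fr)
    rf@responsive
  })
  ## independent oracle for the same statistic: max of a smoothed
  ## standard-normal field on the stimulus grid
  nr <- length(unique(ev$row)); nc <- length(unique(ev$col))
  nullRate <- mean(replicate(300, {
    m <- matrix(rnorm(nr * nc), nr, nc)
    m <- (m - mean(m)) / sqrt(mean((m - mean(m))^2))
    max(retinomap:::gaussianBlur(m, 1)) > 2
  }))
  expect_lt(mean(hits), max(0.15, nullRate + 0.15))
})

test_that("rf centers follow the threshold-sum-centroid definition", {
  mk <- function(zOn, zOff) {
    up <- nrow(zOn)
    new("RfMaps", on = zOn, off = zOff, zOn = zOn, zOff = zOff,
        gridAltDeg = seq_len(up), gridAziDeg = seq_len(ncol(zOn)),
        upAltDeg = seq_len(up), upAziDeg = seq_len(ncol(zOn)),
        responsive = TRUE)
  }
  ## single symmetric peak: center at the peak
  z <- matrix(0, 11, 11)
  z[5:7, 5:7] <- c(1, 2, 1, 2, 5, 2, 1, 2, 1)
  rf <- mk(z, matrix(0, 11, 11))
  expect_equal(unname(rfCenter(rf)), c(6, 6))
  ## two equal peaks at +-d: midpoint
  z2 <- matrix(0, 11, 11); z2[6, 3] <- 4; z2[6, 9] <- 4
  expect_equal(unname(rfCenter(mk(z2, matrix(0, 11, 11)))), c(6, 6))
  ## random maps against an explicit threshold-loop oracle
  set.seed(5)
  zr <- matrix(runif(121), 11, 11); zf <- matrix(runif(121), 11, 11)
  got <- rfCenter(mk(zr, zf))
  thr <- 0.4 * max(max(zr), max(zf))
  a <- zr; a[a < thr] <- 0; b <- zf; b[b < thr] <- 0
  s <- a + b
  want <- c(sum(rowSums(s) * 1:11), sum(colSums(s) * 1:11)) / sum(s)
  expect_equal(unname(got), want)
})

test_that("ten-fold contamination is removed by subtraction (center stress test)", {
  ses <- fxTwoPhoton()
  centers <- function(measured) t(vapply(seq_len(ncol(measured)),
    function(i) {
      fit <- estimateNeuropilRatio(measured[, i], ses$neuropil[, i])
      rf <- computeRfMaps(fit$corrected, ses$events, ses$frameRate)
      rfCenter(rf)
    }, numeric(2)))
  c0 <- centers(ses$measured)
  c1 <- centers(ses$measured + 10 * ses$neuropil)
  expect_lt(max(abs(c1 - c0)), ses$spec@squareSizeDeg)
})

test_that("somata share tuning with their local neuropil", {
  ses <- fxTwoPhoton()
  diffs <- vapply(seq_len(nrow(ses$cells)), function(i) {
    rfN <- computeRfMaps(1 + ses$neuropil[, i], ses$events, ses$frameRate)
    if (!rfN@responsive) return(NA_real_)
    ctr <- rfCenter(rfN)
    sqrt(sum((ctr - unlist(ses$cells[i, c("rfAltDeg", "rfAziDeg")]))^2))
  }, numeric(1))
  expect_gt(mean(diffs < 5, na.rm = TRUE), 0.9)
})

test_that("border profiles are V-shaped with steeper slope on the LM side", {
  ses <- fixture("twoPhotonBig",
    simulateTwoPhotonSession(nCells = 40, seed = 5,
      spec = SparseNoiseSpec(repeatsPerPolarity = 6)))
  border <- rbind(c(0, -300), c(0, 300))   # vertical line at x = 0
  prof <- borderDistanceProfile(ses$cells$somaXUm, ses$cells$somaYUm,
                                ses$cells$rfAltDeg, ses$cells$rfAziDeg,
                                border, binUm = 20)
  ## signed distance: somata on the border read 0, (30, 40) from a
  ## horizontal border reads 40
  d0 <- borderDistanceProfile(0, 0, 0, 0, border)$distanceUm
  expect_equal(abs(d0), 0)
  dxy <- borderDistanceProfile(30, 40, 0, 0,
                               rbind(c(-100, 0), c(100, 0)))$distanceUm
  expect_equal(abs(dxy), 40)
  ## azimuth minimum within one bin of the injected border
  p <- prof$profile
  expect_lt(abs(p$binCenterUm[which.min(p$meanAzi)]), 40)
  ## cortical magnification asymmetry: LM side slope steeper
  d <- prof$distanceUm
  lm <- ses$cells$side == "LM" & abs(d) > 20
  v1 <- ses$cells$side == "V1" & abs(d) > 20
  slopeLM <- stats::coef(stats::lm(ses$cells$rfAziDeg[lm] ~ abs(d[lm])))[2]
  slopeV1 <- stats::coef(stats::lm(ses$cells$rfAziDeg[v1] ~ abs(d[v1])))[2]
  expect_gt(slopeLM, slopeV1)
})
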
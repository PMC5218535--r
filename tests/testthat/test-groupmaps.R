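v1Of <- function(pm) patchTable(pm)$id[which.max(patchTable(pm)$nPixels)]

test_that("alignment recovers an applied rotation within half a degree", {
  maps <- fxGtMaps()
  rotAll <- function(a) PositionMaps(
    retinomap:::rotateMatrix(maps@altitude, a),
    retinomap:::rotateMatrix(maps@azimuth, a),
    retinomap:::rotateMatrix(maps@amplitude, a, fill = 0),
    pixelSizeUm = 25)
  mr <- rotAll(10)
  pmr <- suppressMessages(segmentPatches(mr))
  al <- alignMap(mr, pmr, v1 = v1Of(pmr))
  expect_equal(al$transform$rotationDeg, -10, tolerance = 0.5)
})

test_that("aligning an already aligned map is the identity", {
  maps <- fxGtMaps()
  pm <- fxSegmentedGt()
  al <- alignMap(maps, pm, v1 = v1Of(pm))
  al2 <- alignMap(al$maps, suppressMessages(segmentPatches(al$maps)),
                  v1 = v1Of(suppressMessages(segmentPatches(al$maps))))
  expect_equal(al2$transform$rotationDeg, 0, tolerance = 0.5)
  expect_lt(max(abs(al2$transform$translationPx)), 1.5)
  expect_error(alignMap(maps, pm, v1 = "NoSuchArea"), "V1")
})

test_that("landmark offsets are subtracted so the border point reads zero", {
  maps <- fxGtMaps()
  pm <- fxSegmentedGt()
  pt <- c(26, 72)   # inside V1, near the LM/RL corner
  al <- alignMap(maps, pm, v1 = v1Of(pm), borderPoint = pt)
  expect_equal(al$transform$altitudeOffsetDeg, maps@altitude[pt[1], pt[2]])
  expect_equal(al$transform$azimuthOffsetDeg, maps@azimuth[pt[1], pt[2]])
  ## the aligned map is shifted by exactly those offsets
  al0 <- alignMap(maps, pm, v1 = v1Of(pm))
  v <- validMask(al$maps) & validMask(al0$maps)
  expect_equal(max(abs((altitude(al0$maps) - altitude(al$maps))[v] -
                         al$transform$altitudeOffsetDeg)), 0,
               tolerance = 1e-9)
})

test_that("phasor averaging reproduces inputs and cancels symmetric phases", {
  maps <- fxGtMaps()
  mm <- meanMaps(list(maps, maps), segment = FALSE)
  v <- validMask(mm$maps) & validMask(maps)
  expect_lt(max(abs(altitude(mm$maps)[v] - maps@altitude[v])), 1e-9)
  ## two positions symmetric about the extent midpoint average to it
  mk <- function(p) PositionMaps(altitude = matrix(p, 2, 2),
                                 azimuth = matrix(p, 2, 2))
  mmSym <- meanMaps(list(mk(40), mk(60)), altitudeExtent = c(0, 100),
                    azimuthExtent = c(0, 100), segment = FALSE)
  expect_equal(altitude(mmSym$maps)[1, 1], 50, tolerance = 1e-9)
  ## order invariance
  m1 <- meanMaps(list(mk(20), mk(30), mk(70)), altitudeExtent = c(0, 100),
                 azimuthExtent = c(0, 100), segment = FALSE)
  m2 <- meanMaps(list(mk(70), mk(20), mk(30)), altitudeExtent = c(0, 100),
                 azimuthExtent = c(0, 100), segment = FALSE)
  expect_equal(altitude(m1$maps), altitude(m2$maps))
})

test_that("phasor means agree with a direct circular-statistics oracle", {
  set.seed(9)
  pos <- runif(7, 0, 100)
  mapsL <- lapply(pos, function(p)
    PositionMaps(altitude = matrix(p, 1, 1), azimuth = matrix(p, 1, 1)))
  mm <- meanMaps(mapsL, altitudeExtent = c(0, 100),
                 azimuthExtent = c(0, 100), segment = FALSE)
  phi <- 2 * pi * pos / 100
  want <- (Arg(mean(exp(1i * phi))) / (2 * pi)) %% 1 * 100
  expect_equal(altitude(mm$maps)[1, 1], want, tolerance = 1e-9)
})

test_that("variance maps are per-pixel population variances", {
  sm <- computeSignMap(fxGtMaps())
  expect_equal(max(varianceMap(list(sm, sm)), na.rm = TRUE), 0)
  mk <- function(v) new("SignMap", values = matrix(v, 2, 2),
                        valid = matrix(TRUE, 2, 2),
                        pixelSizeUm = NA_real_)
  vm <- varianceMap(list(mk(1), mk(-1)))
  expect_true(all(vm == 1))       # population variance of {+1, -1}
  set.seed(4)
  vals <- replicate(5, matrix(runif(4, -1, 1), 2, 2), simplify = FALSE)
  vmR <- varianceMap(lapply(vals, function(v)
    new("SignMap", values = v, valid = matrix(TRUE, 2, 2),
        pixelSizeUm = NA_real_)))
  stack <- simplify2array(vals)
  want <- apply(stack, c(1, 2), function(x) mean(x^2) - mean(x)^2)
  expect_equal(vmR, want, tolerance = 1e-12)
  expect_error(varianceMap(list(mk(1))), "two")
})

test_that("patch incidence counts presence over assessable windows", {
  mkPm <- function(nms) {
    L <- matrix(0L, 4, 4)
    for (i in seq_along(nms)) L[i, ] <- i
    new("PatchMap", labels = L,
        patches = data.frame(id = seq_along(nms),
                             sign = rep(1L, length(nms)),
                             nPixels = rep(4L, length(nms)), name = nms),
        raw = matrix(0, 4, 4), borders = matrix(0L, 0, 2),
        pixelSizeUm = NA_real_)
  }
  full <- matrix(TRUE, 4, 4)
  noWin <- matrix(FALSE, 4, 4)
  pms <- list(mkPm(c("V1", "LM")), mkPm(c("V1", "LM")), mkPm("V1"))
  inc <- patchIncidence(pms, list(full, full, full),
                        list(V1 = c(1, 1), LM = c(2, 2), POR = c(4, 4)))
  expect_equal(inc$nPresent[inc$name == "V1"], 3)
  expect_equal(inc$incidence[inc$name == "V1"], 1)
  expect_equal(inc$nPresent[inc$name == "LM"], 2)
  expect_equal(inc$incidence[inc$name == "LM"], 2 / 3)
  ## POR present in no map but assessable in all: incidence 0
  expect_equal(inc$incidence[inc$name == "POR"], 0)
  ## an area outside every window is not assessable
  inc2 <- patchIncidence(pms, list(noWin, noWin, noWin),
                         list(M = c(4, 4)))
  expect_true(is.na(inc2$incidence))
  expect_equal(inc2$nAssessable, 0)
})

test_that("cluster metric separates tight clusters from the shuffled null", {
  ## all centroids identical: dispersion 0
  cen0 <- data.frame(map = 1:4, name = "X", x = 5, y = 5)
  r0 <- clusterMetric(cen0, nShuffles = 100, seed = 3)
  expect_equal(r0$Ck, 0)
  ## centroids drawn from the pooled null itself: Ck near 1
  set.seed(8)
  cenN <- data.frame(map = rep(1:6, 4), name = rep(letters[1:4], each = 6),
                     x = rnorm(24, 0, 5), y = rnorm(24, 0, 5))
  rN <- clusterMetric(cenN, nShuffles = 500, seed = 3)
  expect_equal(mean(rN$Ck), 1, tolerance = 0.25)
  ## a tight cluster among dispersed ones is significant, with a far
  ## smaller dispersion ratio than any loose group
  cenT <- rbind(data.frame(map = 1:6, name = "tight",
                           x = rnorm(6, 30, 0.2), y = rnorm(6, 0, 0.2)),
                cenN)
  rT <- clusterMetric(cenT, nShuffles = 500, seed = 3)
  expect_true(rT$significant[rT$name == "tight"])
  expect_lt(rT$Ck[rT$name == "tight"], 0.1)
  expect_true(all(rT$Ck[rT$name %in% letters[1:4]] >
                    5 * rT$Ck[rT$name == "tight"]))
  ## too few centroids: flagged not assessable
  few <- clusterMetric(data.frame(map = 1:2, name = "Y", x = 1:2, y = 1:2),
                       nShuffles = 10)
  expect_true(is.na(few$Ck))
})
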
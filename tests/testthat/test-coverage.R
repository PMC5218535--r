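gridMaps <- function(n = 20) {
  azi <- outer(rep(1, n), seq_len(n))   # azimuth grows with column
  alt <- outer(n:1, rep(1, n))          # altitude grows bottom -> top
  PositionMaps(altitude = alt, azimuth = azi, pixelSizeUm = 25)
}

test_that("patch coverage marks occupied cells and reports deg^2 areas", {
  maps <- gridMaps()
  one <- matrix(FALSE, 20, 20); one[5, 5] <- TRUE
  cm <- patchCoverage(one, maps)
  expect_equal(coverageArea(cm), 1)
  expect_equal(sum(cm@grid), 1)
  ## a full d x d degree square covers ~ d^2
  sq <- matrix(FALSE, 20, 20); sq[3:12, 3:12] <- TRUE
  expect_equal(coverageArea(patchCoverage(sq, maps)), 100)
  empty <- patchCoverage(matrix(FALSE, 20, 20), maps)
  expect_equal(coverageArea(empty), 0)
  ## simulated V1 with a known transform: area within 5 percent of the
  ## ground-truth rectangle (47 pixel steps of 0.9 x 0.7 degrees)
  atlas <- fxAtlas()
  cmV1 <- patchCoverage(atlas@areas$V1$mask, fxGtMaps())
  expect_equal(coverageArea(cmV1), (47 * 0.9) * (47 * 0.7),
               tolerance = 0.05)
})

test_that("center of coverage is the occupied-cell centroid", {
  maps <- gridMaps()
  sq <- matrix(FALSE, 20, 20); sq[6:10, 9:13] <- TRUE
  cm <- patchCoverage(sq, maps, extentDeg = c(0, 21, 0, 21))
  ctr <- centerOfCoverage(cm)
  ## brute-force centroid over occupied cell centers
  cc <- retinomap:::coverageCellCenters(cm)
  idx <- which(cm@grid, arr.ind = TRUE)
  expect_equal(unname(ctr["altitude"]), mean(cc$alt[idx[, 1]]))
  expect_equal(unname(ctr["azimuth"]), mean(cc$azi[idx[, 2]]))
  ## two cells at symmetric offsets average to the midpoint
  g <- cm; g@grid[] <- FALSE
  g@grid[2, 3] <- TRUE; g@grid[8, 3] <- TRUE
  mid <- centerOfCoverage(g)
  expect_equal(unname(mid["altitude"]), mean(cc$alt[c(2, 8)]))
  expect_error(centerOfCoverage(methods::initialize(g,
    grid = matrix(FALSE, nrow(g@grid), ncol(g@grid)))), "empty")
})

test_that("eccentricity maps give angular distance from the reference", {
  maps <- gridMaps()
  ref <- c(10, 10)
  e <- eccentricityOf(maps, ref)
  expect_equal(e[maps@altitude == 10 & maps@azimuth == 10], 0)
  expect_equal(e[maps@altitude == 14 & maps@azimuth == 13], 5)  # 3-4-5
  ## brute-force loop oracle
  want <- sqrt((maps@altitude - 10)^2 + (maps@azimuth - 10)^2)
  expect_equal(e, want)
  ## great-circle distance shrinks with altitude away from the equator
  eg <- eccentricityOf(maps, c(0, 10), metric = "greatcircle")
  ee <- eccentricityOf(maps, c(0, 10), metric = "euclidean")
  expect_true(all(eg <= ee + 1e-9))
  expect_error(eccentricityOf(maps, c(NA, 0)))
})

test_that("overlaps and quadrant fractions match cell-by-cell counting", {
  maps <- gridMaps()
  ext <- c(0, 21, 0, 21)
  mk <- function(m) patchCoverage(m, maps, extentDeg = ext)
  a <- matrix(FALSE, 20, 20); a[3:10, 3:10] <- TRUE
  b <- matrix(FALSE, 20, 20); b[7:14, 7:14] <- TRUE
  masks <- list(A = mk(a), B = mk(b))
  res <- overlapAndQuadrants(masks, reference = c(10.5, 10.5))
  expect_equal(res$overlapDeg2["A", "A"], coverageArea(masks$A))
  want <- sum(masks$A@grid & masks$B@grid)
  expect_equal(res$overlapDeg2["A", "B"], want)
  ## a mask entirely above and nasal of the reference
  un <- matrix(FALSE, 20, 20); un[3:6, 3:6] <- TRUE   # high alt, low azi
  res2 <- overlapAndQuadrants(list(U = mk(un)), reference = c(2, 10))
  expect_equal(res2$quadrants$upperNasal, 1)
  ## brute-force quadrant count for the random-ish mask
  cc <- retinomap:::coverageCellCenters(masks$A)
  idx <- which(masks$A@grid, arr.ind = TRUE)
  fracUN <- mean(cc$alt[idx[, 1]] >= 10.5 & cc$azi[idx[, 2]] < 10.5)
  expect_equal(res$quadrants$upperNasal[1], fracUN)
  small <- patchCoverage(a, maps, resolutionDeg = 2)
  expect_error(overlapAndQuadrants(list(masks$A, small), c(0, 0)), "grid")
})

test_that("coverage expansion dilates by the receptive-field radius", {
  maps <- gridMaps()
  one <- matrix(FALSE, 20, 20); one[10, 10] <- TRUE
  cm <- patchCoverage(one, maps)
  expect_identical(expandCoverage(cm, 0), cm)
  ex <- expandCoverage(cm, 8)
  expect_equal(coverageArea(ex), pi * 64, tolerance = 0.05)
  ## expansion is monotone and never loses cells
  sq <- matrix(FALSE, 20, 20); sq[4:9, 11:16] <- TRUE
  base <- patchCoverage(sq, maps)
  e2 <- expandCoverage(base, 2); e5 <- expandCoverage(base, 5)
  expect_gte(coverageArea(e2), coverageArea(base))
  expect_gte(coverageArea(e5), coverageArea(e2))
  expect_error(expandCoverage(base, -1))
})

test_that("coverage of a union of disjoint patches is the union of coverages", {
  maps <- gridMaps()
  ext <- c(0, 21, 0, 21)
  a <- matrix(FALSE, 20, 20); a[2:6, 2:6] <- TRUE
  b <- matrix(FALSE, 20, 20); b[12:16, 12:16] <- TRUE
  cu <- patchCoverage(a | b, maps, extentDeg = ext)
  ca <- patchCoverage(a, maps, extentDeg = ext)
  cb <- patchCoverage(b, maps, extentDeg = ext)
  expect_identical(cu@grid, ca@grid | cb@grid)
})

test_that("per-patch coverage summaries line up with the atlas", {
  pm <- fxSegmentedGt()
  cov <- coverageByPatch(pm, fxGtMaps())
  expect_equal(nrow(cov$summary), nrow(patchTable(pm)))
  big <- which.max(cov$summary$areaDeg2)     # V1 has the largest coverage
  expect_equal(cov$summary$sign[big], -1)
  expect_equal(cov$summary$areaDeg2[big], (47 * 0.9) * (47 * 0.7),
               tolerance = 0.1)
})
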
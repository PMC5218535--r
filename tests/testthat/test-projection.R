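fxProj <- function() fixture("proj", {
  sim <- simulateProjectionExperiments()
  fld <- weightedSourceField(sim$experiments)
  dep <- solveDepthField(sim$masks$cortex, sim$masks$pia, sim$masks$wm)
  surf <- projectToSurface(fld, dep)
  list(sim = sim, fld = fld, dep = dep, surf = surf)
})

test_that("weighted source fields average injection centers by strength", {
  d <- c(6L, 6L, 4L)
  ft1 <- array(0, d); ft1[2, 2, 2] <- 3; ft1[4, 4, 2] <- 1
  ex1 <- list(sourceCenter = c(1, 1, 1), Fs = 2, Ft = ft1)
  f1 <- weightedSourceField(list(ex1))
  ## one experiment: every connected voxel points at its source center
  expect_equal(f1@L[2, 2, 2, ], c(1, 1, 1))
  expect_equal(f1@L[4, 4, 2, ], c(1, 1, 1))
  expect_true(is.na(f1@L[1, 1, 1, 1]))
  ## two experiments with equal weight at a voxel: midpoint
  ft2 <- array(0, d); ft2[2, 2, 2] <- 3
  ex2 <- list(sourceCenter = c(5, 3, 1), Fs = 2, Ft = ft2)
  f12 <- weightedSourceField(list(ex1, ex2))
  expect_equal(f12@L[2, 2, 2, ], c(3, 2, 1))
  ## random weights against a brute-force loop
  set.seed(12)
  exs <- lapply(1:4, function(i)
    list(sourceCenter = runif(3, 0, 10), Fs = runif(1, 0.5, 2),
         Ft = array(runif(prod(d)), d)))
  got <- weightedSourceField(exs)
  v <- c(3, 5, 2)
  w <- vapply(exs, function(e) e$Ft[v[1], v[2], v[3]] / e$Fs, numeric(1))
  want <- colSums(do.call(rbind, lapply(exs, `[[`, "sourceCenter")) * w) /
    sum(w)
  expect_equal(got@L[v[1], v[2], v[3], ], want)
  ## invariance under scaling one experiment's Ft and Fs together
  exsScaled <- exs
  exsScaled[[2]]$Ft <- exsScaled[[2]]$Ft * 7
  exsScaled[[2]]$Fs <- exsScaled[[2]]$Fs * 7
  expect_equal(weightedSourceField(exsScaled)@L, got@L)
})

test_that("the slab depth field is linear with interior values in (0, 1)", {
  p <- fxProj()
  nz <- dim(p$dep@depth)[3]
  prof <- p$dep@depth[20, 20, ]
  expect_equal(prof, seq(0, 1, length.out = nz), tolerance = 1e-4)
  ## equipotential at mid-thickness is 0.5 (between the two middle layers
  ## of the even-layered slab)
  expect_equal(mean(p$dep@depth[10, 30, nz / 2 + 0:1]), 0.5,
               tolerance = 1e-4)
  interior <- p$dep@depth[, , 2:(nz - 1)]
  expect_true(all(interior > 0 & interior < 1))
  ## error paths
  m <- array(TRUE, c(4, 4, 4))
  expect_error(solveDepthField(m, array(FALSE, dim(m)), m & FALSE), "empty")
  split <- array(FALSE, c(5, 1, 3)); split[c(1, 5), 1, ] <- TRUE
  pia <- array(FALSE, dim(split)); pia[c(1, 5), 1, 1] <- TRUE
  wm <- array(FALSE, dim(split)); wm[c(1, 5), 1, 3] <- TRUE
  expect_error(solveDepthField(split, pia, wm), "disconnected")
})

test_that("a curved (annulus) cortex matches the log-radial closed form", {
  n <- 71
  ctr <- (n + 1) / 2
  rr <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  rIn <- 12; rOut <- 32
  pia2 <- rr >= rIn - 0.5 & rr < rIn + 0.5
  wm2 <- rr > rOut - 0.5 & rr <= rOut + 0.5
  cortex2 <- rr >= rIn + 0.5 & rr <= rOut - 0.5
  as3 <- function(m) array(m, c(n, n, 1))
  dep <- solveDepthField(as3(cortex2), as3(pia2), as3(wm2), tol = 1e-7)
  sel <- cortex2 & rr > rIn + 1.5 & rr < rOut - 1.5
  want <- log(rr[sel] / rIn) / log(rOut / rIn)
  expect_lt(max(abs(dep@depth[, , 1][sel] - want)), 0.01)
})

test_that("surface projection respects the depth window and picks peak strength", {
  ## hand-built column: strongest voxel too deep, next strongest in range
  d <- c(3L, 3L, 11L)
  ws <- array(0, d)
  L <- array(NA_real_, c(d, 3))
  ws[2, 2, 4] <- 5                      # depth 0.3: in range
  L[2, 2, 4, ] <- c(1, 1, 1)
  ws[2, 2, 8] <- 50                     # depth 0.7: out of range
  L[2, 2, 8, ] <- c(9, 9, 9)
  fld <- new("ProjectionField", L = L, weightSum = ws)
  zi <- slice.index(array(0, d), 3)
  dep <- solveDepthField(zi > 1 & zi < d[3], zi == 1, zi == d[3])
  surf <- projectToSurface(fld, dep)
  expect_equal(surf$AP[2, 2], 1)        # the in-range voxel wins
  expect_true(is.na(surf$AP[1, 1]))
  ## a single connected voxel at depth 0.3 reaches the surface
  ws2 <- array(0, d); ws2[3, 1, 4] <- 1
  L2 <- array(NA_real_, c(d, 3)); L2[3, 1, 4, ] <- c(7, 2, 0)
  surf2 <- projectToSurface(new("ProjectionField", L = L2,
                                weightSum = ws2), dep)
  expect_equal(surf2$AP[3, 1], 7)
  expect_equal(surf2$ML[3, 1], 2)
})

test_that("synthetic retinotopic projections reproduce the injected mapping", {
  p <- fxProj()
  ok <- is.finite(p$surf$AP) & is.finite(p$sim$truthAP)
  expect_gt(sum(ok), 300)
  expect_lt(max(abs(p$surf$AP[ok] - p$sim$truthAP[ok])), 1)
  expect_lt(max(abs(p$surf$ML[ok] - p$sim$truthML[ok])), 1)
})

test_that("projection sign maps yield mirrored opposite-sign patches", {
  p <- fxProj()
  psm <- suppressMessages(projectionSignMap(p$surf))
  tabH <- patchTable(psm$patchesHigh)
  expect_equal(nrow(tabH), 2)
  expect_setequal(tabH$sign, c(-1L, 1L))
  ## the functional sign map of the same geometry agrees in sign
  maps <- PositionMaps(altitude = p$surf$AP, azimuth = p$surf$ML)
  sm <- computeSignMap(maps)
  for (i in tabH$id) {
    med <- stats::median(sm@values[patchMask(psm$patchesHigh, i)],
                         na.rm = TRUE)
    expect_equal(sign(med), tabH$sign[tabH$id == i])
  }
  ## the lower threshold never shrinks a patch: every high-threshold
  ## patch pixel set is contained in some low-threshold patch
  tabL <- patchTable(psm$patchesLow)
  expect_equal(nrow(tabL), 2)
  LH <- labelImage(psm$patchesHigh); LL <- labelImage(psm$patchesLow)
  for (i in tabH$id) {
    inside <- LL[LH == i]
    cover <- max(table(inside[inside > 0])) / sum(LH == i)
    expect_gt(cover, 0.95)
  }
  expect_gte(sum(LL > 0), sum(LH > 0))
})
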
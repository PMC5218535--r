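## Shared fixtures, memoized so expensive simulations run once per suite.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

fxAtlas <- function() fixture("atlas", buildDefaultAtlas())

fxGtMaps <- function() fixture("gtMaps", atlasPositionMaps(fxAtlas()))

## Noise-free four-direction mapping session at the default acquisition
## settings (10 Hz, two stimulus periods per direction).
fxSession <- function() fixture("session", {
  cfg <- SimulationConfig(noiseSd = 0, nCycles = 2)
  simulateMappingSession(fxAtlas(), config = cfg)
})

fxRecoveredMaps <- function() fixture("recoveredMaps",
  extractPositionMaps(fxSession()))

fxSegmentedGt <- function() fixture("segmentedGt",
  suppressMessages(segmentPatches(fxGtMaps())))

fxSegmentedRecovered <- function() fixture("segmentedRecovered",
  suppressMessages(segmentPatches(fxRecoveredMaps())))

## Small two-photon session (reduced repeats keep the suite fast; the
## statistics that matter — tuned neuropil, fast shared fluctuation,
## mirrored soma layout — match the generator defaults).
fxTwoPhoton <- function() fixture("twoPhoton",
  simulateTwoPhotonSession(nCells = 8, seed = 2,
    spec = SparseNoiseSpec(repeatsPerPolarity = 10)))

## Compact single-area atlas for noise studies (small enough to simulate
## many trials quickly).
fxSmallAtlas <- function() fixture("smallAtlas", {
  dims <- c(24L, 24L)
  sAz <- 14 / 15; sAl <- 11 / 15
  tr <- matrix(c(sAz, 0, 0, -sAl, -5 * sAz, 5 + 5 * sAl), 2, 3)
  area <- retinomap:::areaFromRect(dims, 5:20, 5:20, tr)
  methods::new("CorticalAtlas", dims = dims, pixelSizeUm = 25,
               areas = list(V1 = area))
})

## Match recovered patches to ground-truth areas by maximal overlap.
## Returns per-patch matches plus overall pixel agreement over GT pixels.
matchToAtlas <- function(pm, atlas) {
  gtL <- labelImage(atlas)
  L <- labelImage(pm)
  sg <- fieldSign(atlas)
  rows <- lapply(patchTable(pm)$id, function(i) {
    ov <- table(gtL[L == i & gtL > 0])
    if (!length(ov)) return(data.frame(id = i, gtArea = NA, gtSign = NA,
                                       overlap = 0))
    best <- as.integer(names(ov)[which.max(ov)])
    data.frame(id = i, gtArea = names(atlas@areas)[best],
               gtSign = sg[[best]], overlap = max(ov))
  })
  m <- do.call(rbind, rows)
  agree <- 0
  for (k in seq_len(nrow(m)))
    if (!is.na(m$gtArea[k])) {
      gtId <- match(m$gtArea[k], names(atlas@areas))
      agree <- agree + sum(L == m$id[k] & gtL == gtId)
    }
  list(matches = m, pixelAgreement = agree / sum(gtL > 0))
}

## Border pixels lying between two specific patches of a PatchMap.
pairBorderPixels <- function(pm, idA, idB) {
  L <- labelImage(pm)
  b <- pm@borders
  if (!nrow(b)) return(b)
  keep <- vapply(seq_len(nrow(b)), function(k) {
    r <- b[k, 1]; c <- b[k, 2]
    rr <- max(1, r - 1):min(nrow(L), r + 1)
    cc <- max(1, c - 1):min(ncol(L), c + 1)
    nb <- L[rr, cc]
    any(nb == idA) && any(nb == idB)
  }, logical(1))
  b[keep, , drop = FALSE]
}

## Largest nearest-neighbour distance from pixel set a to pixel set b.
maxNearestDistance <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(Inf)
  max(vapply(seq_len(nrow(a)), function(i)
    min(sqrt((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2)), numeric(1)))
}
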
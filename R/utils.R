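#' @include AllClasses.R
NULL

## Run code with a temporary RNG state seeded from `seed`, restoring the
## caller's stream afterwards.
withLocalSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Central-difference gradient of a matrix (one-sided at the edges), in the
## style of numpy.gradient: returns d/drow and d/dcol.
matrixGradient <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  dr <- m; dc <- m
  if (nr >= 3) dr[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  if (nr >= 2) { dr[1, ] <- m[2, ] - m[1, ]; dr[nr, ] <- m[nr, ] - m[nr - 1, ] }
  if (nr == 1) dr[] <- 0
  if (nc >= 3) dc[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  if (nc >= 2) { dc[, 1] <- m[, 2] - m[, 1]; dc[, nc] <- m[, nc] - m[, nc - 1] }
  if (nc == 1) dc[] <- 0
  list(drow = dr, dcol = dc)
}

## Separable Gaussian blur with NA-aware, edge-normalized weighting:
## truncated kernel mass (at image edges or next to NA pixels) is
## renormalized away, so masked maps blur without bleeding NAs.  Works for
## kernels larger than the image, unlike FFT-based filters.
gaussianBlur <- function(m, sigmaPx) {
  if (!is.finite(sigmaPx) || sigmaPx < 0.3) return(m)
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- stats::dnorm(d, sd = sigmaPx)
    k[d > ceiling(3 * sigmaPx)] <- 0
    k
  }
  Gr <- band(nrow(m)); Gc <- band(ncol(m))
  na <- !is.finite(m)
  m0 <- m; m0[na] <- 0
  w <- Gr %*% ((!na) * 1) %*% Gc
  out <- (Gr %*% m0 %*% Gc) / pmax(w, 1e-12)
  out[na] <- NA_real_
  out
}

## Bilinear sampling of matrix `m` at fractional (row, col) positions.
## Out-of-range positions return `fill`.
bilinearSample <- function(m, rows, cols, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= nr & c0 + 1 <= nc
  out <- rep(fill, length(rows))
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok]); i10 <- cbind(r0[ok] + 1, c0[ok])
    i01 <- cbind(r0[ok], c0[ok] + 1); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- m[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      m[i10] * fr[ok] * (1 - fc[ok]) +
      m[i01] * (1 - fr[ok]) * fc[ok] +
      m[i11] * fr[ok] * fc[ok]
  }
  out
}

## Rotate a matrix about its centroid (or a given center) by `angleDeg`
## (counter-clockwise in standard row/col display terms), resampling
## bilinearly on the same grid.
rotateMatrix <- function(m, angleDeg, center = NULL, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  if (is.null(center)) center <- c((nr + 1) / 2, (nc + 1) / 2)
  th <- angleDeg * pi / 180
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  dr <- g$row - center[1]; dc <- g$col - center[2]
  srcR <- center[1] + cos(th) * dr - sin(th) * dc
  srcC <- center[2] + sin(th) * dr + cos(th) * dc
  matrix(bilinearSample(m, srcR, srcC, fill = fill), nr, nc)
}

## Number of 8-connected components among a small set of pixel coordinates.
## Used for per-cell redundancy checks where sets are tiny.
nComponents8 <- function(rows, cols) {
  n <- length(rows)
  if (n <= 1) return(n)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (max(abs(rows[i] - rows[j]), abs(cols[i] - cols[j])) <= 1) {
      ri <- findRoot(i); rj <- findRoot(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), findRoot, integer(1))))
}

## Cubic-spline up-sampling of a matrix by an integer factor, separable
## (rows then columns), evaluated at cell-center positions of the fine grid.
splineUpsample <- function(m, factor) {
  nr <- nrow(m); nc <- ncol(m)
  fineR <- (seq_len(nr * factor) - 0.5) / factor + 0.5
  fineC <- (seq_len(nc * factor) - 0.5) / factor + 0.5
  tmp <- matrix(0, nr * factor, nc)
  for (j in seq_len(nc))
    tmp[, j] <- stats::spline(seq_len(nr), m[, j], xout = fineR,
                              method = "natural")$y
  out <- matrix(0, nr * factor, nc * factor)
  for (i in seq_len(nr * factor))
    out[i, ] <- stats::spline(seq_len(nc), tmp[i, ], xout = fineC,
                              method = "natural")$y
  out
}

## Weighted centroid of matrix cells given per-axis coordinates.
weightedCentroid <- function(w, rowCoord, colCoord) {
  tot <- sum(w)
  if (tot <= 0) stop("weighted centroid of an all-zero map is undefined")
  c(sum(rowSums(w) * rowCoord) / tot, sum(colSums(w) * colCoord) / tot)
}

## Centroid (row, col) of a logical mask.
maskCentroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask has no centroid")
  c(mean(idx[, 1]), mean(idx[, 2]))
}

## Disc structuring element of the given radius in pixels.
discBrush <- function(radiusPx) {
  size <- 2 * max(1, round(radiusPx)) + 1
  EBImage::makeBrush(size, shape = "disc")
}

## Dilate a logical mask by a disc of `radiusPx` pixels.
dilateMask <- function(mask, radiusPx) {
  if (radiusPx <= 0) return(mask)
  as.matrix(EBImage::dilate(mask * 1, discBrush(radiusPx))) > 0.5
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
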
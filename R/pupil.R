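#' @include AllClasses.R utils.R
NULL

#' Simulate an infrared eye video
#'
#' Renders a dark pupil ellipse on a bright sclera with a small, fixed LED
#' glint.  The eye is modeled as a sphere of radius \code{eyeRadiusMm}
#' (1.7 mm); a gaze rotation of theta displaces the pupil image by
#' \code{eyeRadius * sin(theta)} from the glint (azimuth: horizontal,
#' altitude: vertical, upward gaze moving the pupil up the image).  During
#' blink intervals a bright lid covers the frame, hiding pupil and glint.
#'
#' @param gazeAziDeg,gazeAltDeg numeric vectors of gaze angles per frame
#'   (degrees, |angle| <= 90).
#' @param pupilRadiusMm pupil radius per frame (scalar or vector, mm).
#' @param blinkFrames integer vector of frames rendered as blinks.
#' @param dims frame size c(rows, cols) in pixels.
#' @param pxSizeMm pixel size (mm; default 0.018).
#' @param eyeRadiusMm eyeball radius (mm).
#' @param noiseSd Gaussian pixel noise SD (luminance units).
#' @param seed noise seed.
#' @return A list of numeric matrices (frames, luminance in [0, 1]).
#' @export
simulatePupilVideo <- function(gazeAziDeg, gazeAltDeg,
                               pupilRadiusMm = 0.5, blinkFrames = integer(0),
                               dims = c(240L, 320L), pxSizeMm = 0.018,
                               eyeRadiusMm = 1.7, noiseSd = 0, seed = 1L) {
  n <- length(gazeAziDeg)
  stopIfNot(length(gazeAltDeg) == n, "gaze vectors must match in length")
  stopIfNot(all(abs(gazeAziDeg) <= 90 & abs(gazeAltDeg) <= 90),
            "|gaze| must be <= 90 degrees")
  pupilRadiusMm <- rep_len(pupilRadiusMm, n)
  ctr <- c(dims[1] / 2, dims[2] / 2)
  glint <- ctr + c(-18, 12)          # fixed LED reflection, off pupil center
  rows <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cols <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  glintMask <- (rows - glint[1])^2 + (cols - glint[2])^2 <= 3^2
  d2r <- pi / 180
  frames <- withLocalSeed(seed, lapply(seq_len(n), function(i) {
    f <- matrix(0.8, dims[1], dims[2])   # sclera
    if (i %in% blinkFrames) {
      f[] <- 0.85                        # lid covers pupil and glint
    } else {
      dx <- eyeRadiusMm * sin(gazeAziDeg[i] * d2r) / pxSizeMm
      dy <- -eyeRadiusMm * sin(gazeAltDeg[i] * d2r) / pxSizeMm
      pc <- ctr + c(dy, dx)
      ## foreshortening: the pupil disk compresses along the gaze direction
      ra <- pupilRadiusMm[i] / pxSizeMm * cos(gazeAltDeg[i] * d2r)
      rz <- pupilRadiusMm[i] / pxSizeMm * cos(gazeAziDeg[i] * d2r)
      pupil <- ((rows - pc[1]) / ra)^2 + ((cols - pc[2]) / rz)^2 <= 1
      f[pupil] <- 0.1
      f[glintMask] <- 1
    }
    if (noiseSd > 0)
      f <- pmin(1, pmax(0, f + matrix(stats::rnorm(length(f), sd = noiseSd),
                                      dims[1], dims[2])))
    f
  }))
  frames
}

#' Pupil area from a pixel count
#'
#' @param nPixels number of pixels inside the pupil outline.
#' @param pixelAreaMm2 area of one pixel (default 3.24e-4 mm^2).
#' @return Area in mm^2.
#' @examples
#' pupilAreaMm2(100)   # 0.0324
#' @export
pupilAreaMm2 <- function(nPixels, pixelAreaMm2 = 3.24e-4)
  nPixels * pixelAreaMm2

## Shape features of the candidate outlines in a label image.
candidateFeatures <- function(lab, frame) {
  ids <- setdiff(unique(as.vector(lab)), 0)
  t(vapply(ids, function(i) {
    m <- lab == i
    idx <- which(m, arr.ind = TRUE)
    area <- nrow(idx)
    ## perimeter: pixels of the object with a 4-neighbour outside it
    per <- 0
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb <- cbind(idx[, 1] + sh[1], idx[, 2] + sh[2])
      inside <- nb[, 1] >= 1 & nb[, 1] <= nrow(m) &
        nb[, 2] >= 1 & nb[, 2] <= ncol(m)
      val <- rep(FALSE, area)
      val[inside] <- m[nb[inside, , drop = FALSE]]
      per <- per + sum(!val)
    }
    c(id = i, cy = mean(idx[, 1]), cx = mean(idx[, 2]), area = area,
      intensity = mean(frame[m]),
      roundness = 4 * pi * area / max(per, 1)^2)
  }, numeric(6)))
}

#' Detect the pupil and LED glint in one frame
#'
#' The brightest object is located and masked (the corneal LED reflection);
#' the frame is blurred and dark objects inside the region of interest are
#' outlined, opened morphologically, and filtered by the minimum area
#' (0.03 mm^2).  Candidates are ranked against the previous pupil on
#' centroid distance, area, mean intensity and roundness
#' (4 pi area / perimeter^2); the smallest summed rank wins.  Without a
#' previous state the largest, most circular dark outline wins by the same
#' rank-sum rule over size and roundness.  A frame without a glint is a
#' blink; a frame with a glint but no surviving candidate is flagged lost.
#'
#' @param frame numeric matrix, grayscale luminance.
#' @param previous the previous \linkS4class{PupilState}, or NULL.
#' @param roi optional logical matrix restricting the pupil search.
#' @param pxSizeMm pixel size (mm); pixel area is its square.
#' @param glintFloor minimum luminance of the glint (blink below this).
#' @param darkThreshold luminance below which pixels count as dark; the
#'   default sits midway between a dark pupil and a bright sclera so the
#'   blurred edge is cut at the true outline.
#' @param blurSigmaPx Gaussian blur applied before outlining.
#' @param minAreaMm2 minimum outline area (mm^2; default 0.03).
#' @return A \linkS4class{PupilState}.
#' @export
detectPupil <- function(frame, previous = NULL, roi = NULL,
                        pxSizeMm = 0.018, glintFloor = 0.95,
                        darkThreshold = 0.45, blurSigmaPx = 1,
                        minAreaMm2 = 0.03) {
  pixelArea <- pxSizeMm^2
  mx <- max(frame)
  if (mx < glintFloor)                      # eyelid closed: no reflection
    return(new("PupilState", centroidPx = c(NA_real_, NA_real_),
               glintPx = c(NA_real_, NA_real_), areaMm2 = NA_real_,
               blink = TRUE, lost = FALSE, outline = matrix(0L, 0, 2)))
  bright <- frame >= glintFloor
  gl <- as.matrix(EBImage::bwlabel(bright * 1))
  glInt <- vapply(seq_len(max(gl)), function(i) max(frame[gl == i]),
                  numeric(1))
  gMask <- gl == which.max(glInt)
  gIdx <- which(gMask, arr.ind = TRUE)
  glint <- c(mean(gIdx[, 2]), mean(gIdx[, 1]))           # (x, y)
  work <- frame
  work[gMask] <- stats::median(frame)       # mask the reflection
  work <- gaussianBlur(work, blurSigmaPx)
  dark <- work < darkThreshold
  if (!is.null(roi)) dark <- dark & roi
  dark <- as.matrix(EBImage::opening(dark * 1, discBrush(2))) > 0.5
  lab <- as.matrix(EBImage::bwlabel(dark * 1))
  lost <- new("PupilState", centroidPx = c(NA_real_, NA_real_),
              glintPx = glint, areaMm2 = NA_real_, blink = FALSE,
              lost = TRUE, outline = matrix(0L, 0, 2))
  if (max(lab) == 0) return(lost)
  ft <- candidateFeatures(lab, frame)
  ft <- ft[ft[, "area"] * pixelArea >= minAreaMm2, , drop = FALSE]
  if (!nrow(ft)) return(lost)
  if (!is.null(previous) && !previous@blink && !previous@lost) {
    dCent <- sqrt((ft[, "cx"] - previous@centroidPx[1])^2 +
                    (ft[, "cy"] - previous@centroidPx[2])^2)
    dArea <- abs(ft[, "area"] * pixelArea - previous@areaMm2)
    dInt <- ft[, "intensity"]
    dRound <- abs(ft[, "roundness"] - 1)
    rk <- rank(dCent) + rank(dArea) + rank(dInt) + rank(dRound)
  } else {
    rk <- rank(-ft[, "area"]) + rank(-ft[, "roundness"])
  }
  ## ties: larger area, then lower mean intensity
  ord <- order(rk, -ft[, "area"], ft[, "intensity"])
  sel <- ft[ord[1], ]
  outline <- which(lab == sel[["id"]], arr.ind = TRUE)
  new("PupilState", centroidPx = c(sel[["cx"]], sel[["cy"]]),
      glintPx = glint, areaMm2 = sel[["area"]] * pixelArea, blink = FALSE,
      lost = FALSE, outline = outline)
}

#' Track the pupil through a frame sequence
#'
#' Applies \code{\link{detectPupil}} frame by frame, carrying the previous
#' state forward (detection restarts from the size/roundness rule after a
#' blink).
#'
#' @param frames list of grayscale matrices.
#' @param ... passed to \code{\link{detectPupil}}.
#' @return A data.frame with one row per frame: frame, x, y (pupil centroid
#'   px), glintX, glintY, areaMm2, blink, lost.
#' @export
trackPupil <- function(frames, ...) {
  prev <- NULL
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    st <- detectPupil(frames[[i]], previous = prev, ...)
    if (!st@blink && !st@lost) prev <- st
    out[[i]] <- data.frame(frame = i, x = st@centroidPx[1],
                           y = st@centroidPx[2], glintX = st@glintPx[1],
                           glintY = st@glintPx[2], areaMm2 = st@areaMm2,
                           blink = st@blink, lost = st@lost)
  }
  do.call(rbind, out)
}

#' Convert tracked pupil positions to gaze angles
#'
#' The pupil position relative to the LED reflection, expressed as the
#' deviation from its mean over the movie (blink and lost frames excluded
#' from the mean), is converted to gaze angles by
#' \code{delta theta = arcsin(delta / r)} with eyeball radius r = 1.7 mm.
#' Positive azimuth deviation corresponds to rightward image displacement,
#' positive altitude to upward gaze (negative image y).
#'
#' @param track data.frame from \code{\link{trackPupil}}.
#' @param eyeRadiusMm eyeball radius (mm; default 1.7).
#' @param pxSizeMm pixel size (mm; default 0.018).
#' @return The track with added columns \code{dAziDeg}, \code{dAltDeg}
#'   (degrees; NA on blink/lost frames) and \code{gazeValid} (FALSE where
#'   the displacement exceeds the eye radius).
#' @examples
#' tr <- data.frame(frame = 1:2, x = c(10, 10 + 0.85 / 0.018),
#'                  y = c(5, 5), glintX = 0, glintY = 0,
#'                  areaMm2 = 0.1, blink = FALSE, lost = FALSE)
#' ## 0.85 mm displacement on a 1.7 mm eye: arcsin(0.5) = 30 degrees change
#' @export
gazeAngles <- function(track, eyeRadiusMm = 1.7, pxSizeMm = 0.018) {
  ok <- !track$blink & !track$lost & is.finite(track$x)
  relX <- (track$x - track$glintX) * pxSizeMm
  relY <- (track$y - track$glintY) * pxSizeMm
  dx <- relX - mean(relX[ok])
  dy <- relY - mean(relY[ok])
  valid <- ok & abs(dx) <= eyeRadiusMm & abs(dy) <= eyeRadiusMm
  track$dAziDeg <- ifelse(valid, asin(pmax(-1, pmin(1, dx / eyeRadiusMm))) *
                            180 / pi, NA_real_)
  track$dAltDeg <- ifelse(valid, asin(pmax(-1, pmin(1, -dy / eyeRadiusMm))) *
                            180 / pi, NA_real_)
  track$gazeValid <- valid
  track
}

#' Partition mapping trials by eye movement
#'
#' A trial is flagged as containing an eye movement when its maximum
#' excursion from the reference position reaches the threshold (default two
#' degrees) in either gaze axis.
#'
#' @param trialGaze list of data.frames (one per trial) with columns
#'   \code{dAziDeg}, \code{dAltDeg}.
#' @param thresholdDeg movement threshold (degrees).
#' @return A list: \code{movement} and \code{still} (integer trial indices),
#'   plus \code{maxExcursionDeg} per trial.
#' @export
classifyTrials <- function(trialGaze, thresholdDeg = 2) {
  exc <- vapply(trialGaze, function(g) {
    v <- c(abs(g$dAziDeg), abs(g$dAltDeg))
    if (all(is.na(v))) 0 else max(v, na.rm = TRUE)
  }, numeric(1))
  list(movement = which(exc >= thresholdDeg),
       still = which(exc < thresholdDeg),
       maxExcursionDeg = exc)
}
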
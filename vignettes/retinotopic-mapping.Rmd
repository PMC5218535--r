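---
title: "Methods: periodic-stimulus retinotopy, field-sign segmentation, and companion analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: periodic-stimulus retinotopy, field-sign segmentation, and companion analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinomap)
```

## The mapping model

Periodic-stimulus retinotopy drives cortex with a flickering checkerboard
bar that sweeps the visual field at constant speed, repeating at a fixed
frequency (defaults 0.043 Hz for horizontal and 0.048 Hz for vertical
sweeps).  A pixel whose neurons prefer visual position $p$ responds each
time the bar crosses $p$, so its fluorescence trace is periodic at the
sweep frequency with a phase that encodes $p$ through the linear bar
trajectory.  The package extracts, per pixel, the first-harmonic phase
$\varphi$ at the in-band peak frequency and converts it to a position
$p = \mathrm{traj}(\varphi / 2\pi \times T)$, where $T$ is the repetition
period.  Any fixed response latency $d$ biases a single-direction
estimate by $\pm v d$ (9 °/s times the delay); averaging the positions
from opposite sweep directions cancels this bias exactly, which is why a
full session uses all four cardinal directions.

Assumptions: the response is stimulus-locked and approximately linear,
movies are motion-registered, and photobleaching is linear in time (the
default bleaching coefficient, 235 % per J/mm² at 89 µW/mm², corresponds
to about 0.02 % of baseline per second).  Hemodynamic signals are not
modeled or removed.

**Phase estimator.**  The harmonic is located at the discrete Fourier bin
of maximal magnitude inside the analysis band (0.022–0.065 Hz azimuth,
0.024–0.072 Hz altitude), computed over the largest whole number of
repetition periods after stimulus onset.  Phase and amplitude are then
re-estimated by least squares on the design
$[1,\,t,\,\cos\omega t,\,\sin\omega t]$ at that bin frequency.  The joint
fit matters: a linear photobleaching trend is not orthogonal to a
harmonic over a finite window, and subtracting a separately fitted trend
leaks into the phase.  With `detrend = FALSE` the trend column is
dropped, making the estimator an exact bin projection — useful when the
signal is known trend-free, and the configuration under which the
delay-invariance property holds to machine precision.

**Validity.**  Pixels whose in-band amplitude falls below
`minAmplitudeFrac` (default 0.2) of the image maximum are flagged
invalid; the mask propagates through the sign map, segmentation, and
coverage.  On real data this floor separates responsive cortex from the
surround; it is a fraction rather than an absolute value because
illumination and expression vary by orders of magnitude across
preparations.

## Field sign and border identification

The visual field sign is the sine of the angle between the local image
gradients of the azimuth and altitude maps,
$S = \sin(\angle\nabla\mathrm{alt} - \angle\nabla\mathrm{azi})$,
equivalently the sign of the Jacobian determinant of the
cortex-to-visual-field mapping.  The convention is fixed so that
non-mirror (V1-like) maps are negative and their mirror images positive.
Gradients are NA-aware central differences (one-sided at mask edges), so
the sign is defined up to the edge of responsive cortex.

Segmentation proceeds in the stages of the standard border-identification
routine:

1. Gaussian-filter the sign map (`signFilterSigmaUm`, default 8.14 µm).
   Note that at the default 12.9–25 µm pixel sizes this sigma is below
   one pixel, so the filter barely acts; the package emits a note and the
   parameter accepts any value (set it in pixels by leaving the map's
   pixel size `NA`).
2. Threshold at `signThreshold` (default 0.32; the useful range is about
   0.2–0.4): pixels keep their sign, sub-threshold pixels become 0.
3. Open/close with a disc of `openCloseRadiusPx` to remove isolated
   pixels, then label 4-connected components.
4. Grow each component into the surrounding sub-threshold (but valid)
   pixels one ring per iteration; growth stops where fronts of different
   components meet, and a thinning pass guarantees a one-pixel border
   between adjacent patches.  The growth is capped (`growthIter`) so
   patches reclaim the thresholded-out border zone without swallowing
   distant unresponsive cortex.  Where two labels touch, the pixel on the
   higher-numbered side is cleared — an arbitrary but deterministic
   tie-break; mirrored inputs can therefore differ by one pixel along
   borders.
5. Split/merge to a fixed point: a patch whose *internal redundancy*
   exceeds `redundancyThreshold` (0.10) is split by a watershed on the
   visual eccentricity image, seeded at its regional minima with a
   prominence tolerance of `watershedProminenceDeg` (1°); adjacent
   same-sign patches with *pairwise redundancy* below the threshold are
   merged (pairs processed in order of increasing redundancy, ties by
   patch id); patches under `minPatchPixels` (100) are discarded.

**Redundancy definitions.**  The criterion is stated as a coverage
fraction without a normalization; this implementation uses, for a pair,
the overlap of the two coverage masks divided by the smaller coverage
area, and for a single patch the fraction of visual-space cells (1° grid)
whose contributing cortical pixels form two or more disconnected
clusters.  Both reduce to the intuitive notions for idealized maps
(identical patches give 1, disjoint give 0; a patch containing two
complete copies of a region approaches 1).

**Eccentricity reference.**  Splitting uses eccentricity relative to the
centroid of the combined visual coverage of the map — a proxy for the V1
center of coverage that is available before areas are named.  An explicit
reference can be supplied.

## Coverage, group maps, and the cluster metric

Coverage is cell occupancy on a 1° grid (a cell is covered if at least
one patch pixel's preferred position falls in it), not a kernel density;
areas are reported as occupied cells × resolution².  Eccentricity uses
Euclidean distance in (altitude, azimuth) degrees by default, matching
flat coverage plots; great-circle distance is available by flag.
Quadrant fractions divide the field at a reference point, conventionally
the V1 center of coverage.

Cross-animal averaging aligns each map on its V1 centroid, rotates the
principal axis of the azimuth gradient (leading eigenvector of the
gradient second-moment matrix over V1) to a common axis, and optionally
subtracts the visual coordinates of a landmark — the V1/LM/RL border
point — so it reads (0°, 0°).  Mean position maps are computed by vector
summation: positions map to unit phasors over the axis extent, phasors
average per pixel, and the mean phase maps back.  This respects the
circular topology of phase and downweights no map.  The mean sign map is
an arithmetic average, re-segmented at threshold 0.3.

The cluster metric $C_k$ for a patch is its observed centroid dispersion
(mean distance to the group centroid) divided by the expected dispersion
of an equally sized group drawn from the pooled centroids with labels
shuffled (default 1000 shuffles); significance is the observed dispersion
falling below the 0.05 quantile of that null.  The originating literature
does not print the formula, so this normalized-dispersion reading is an
interpretation — documented as such — with the shuffle count and level
configurable.

## Pupil tracking and gaze

The LED corneal reflection is the brightest object; its absence flags a
blink.  After masking the glint and blurring, dark objects inside the
region of interest are outlined by thresholding at the luminance midpoint
between pupil and sclera (so the blurred edge is cut at the true
outline), opened morphologically, and filtered at 0.03 mm².  Candidates
are ranked against the previous pupil on centroid distance, area, mean
intensity, and roundness ($4\pi A / P^2$; the perimeter is the count of
4-connected boundary edges); the minimum rank sum wins, ties broken by
larger area then lower intensity.  Without a previous state the largest,
most circular outline wins.  Gaze angles are
$\Delta\theta = \arcsin(\Delta/r)$ with $r = 1.7$ mm, where $\Delta$ is
the glint-relative pupil displacement minus its movie mean (blink and
lost frames excluded from the mean).  Trials partition at a 2° maximum
excursion.

## Neuropil subtraction and receptive fields

Somatic fluorescence in densely labeled tissue is contaminated by
surrounding neuropil: $F_m = F_{\mathrm{true}} + r\,F_n$.  The package
estimates $r$ as the value minimizing the second-difference roughness of
the corrected trace $F_m - r F_n$; the objective is quadratic, so the
minimizer is the regression slope of the measured trace's curvature on
the neuropil trace's curvature, clipped to $[0, r_{\max}]$.  What makes
$r$ identifiable is the fast frame-to-frame component of the neuropil
signal, which enters the soma only through the contamination; the
stimulus-locked components of soma and neuropil are correlated (they
share tuning) and contribute bias only in proportion to their share of
the curvature power.  The clip ceiling defaults to 20 rather than 1:
robustness tests deliberately add tenfold-amplified neuropil to the
somatic trace, and the estimator must be able to report the resulting
effective ratio near $r + 10$ for the subtraction to remove it.

Receptive fields: per stimulus location and polarity, the mean ΔF/F
integral over 300 ms after onset (baseline 0.5 s before onset) gives raw
On/Off maps; each is z-scored over its own pixels (population SD),
smoothed with a 6° Gaussian, and up-sampled tenfold with cubic splines.
Responsiveness (max z > 2) is judged on the smoothed maps: on an
11 × 13 stimulus grid the maximum of a smoothed standard-normal field
rarely approaches 2, while a genuine receptive field retains a clear
margin — whereas on raw maps the maximum of ~140 independent z values
exceeds 2 for most pure-noise cells.  Centers threshold both maps at
40 % of the larger maximum, sum them, and take the weighted centroid.
Soma–border distances are signed shortest Cartesian distances to the
border polyline (positive on the left of its direction), binned at
20 µm.

## Projection-based retinotopy

Tracer experiments pool into a per-voxel source estimate
$\vec L = \sum_i W_i \vec L_i / \sum_i W_i$ with $W = F_t / F_s$.  The
normalized cortical depth solves the Laplace equation with pia = 0 and
white matter = 1 by red–black successive over-relaxation (tolerance
$10^{-6}$); any solver meeting the boundary conditions is equivalent.
Surface projection follows each column's streamline along the depth
gradient, restricts to normalized depths 0.1–0.5, and copies the
source vector of the voxel with the greatest summed projection strength
(ties: the shallowest voxel, encountered first, wins — the tie rule is
not specified by the procedure itself).  The resulting
anterior–posterior and medial–lateral maps are the anatomical homologues
of altitude and azimuth and feed the same sign-map and border code, at
thresholds 0.2 and, to close inter-area gaps, 0.1.  The synthetic volume
generator uses a 50 µm-scale grid; nothing in the method depends on the
voxel size.

## What the simulator does and does not emulate

The default atlas is a 96 × 96 pixel sheet (25 µm pixels) holding a
central V1-like area and four mirror-image neighbours in the stereotyped
cross arrangement, with affine retinotopic transforms whose per-pixel
steps (0.9° azimuth, 0.7° altitude) stay below the 1° coverage grid so
occupancy areas match the analytic rectangles.  Sweep movies follow the
forward model baseline × (1 − bleach·t) × (1 + amplitude · response) +
noise, where the response is the bar-occupancy boxcar convolved with a
difference-of-exponentials calcium kernel (70 ms rise, 540 ms decay —
the measured GCaMP6f kinetics; any kernel is injectable).  Two stimulus
periods per direction are simulated by default; this keeps a full
four-direction session near fifteen seconds of compute while leaving
two complete cycles for the spectral estimate.

Deliberately not modeled: hemodynamic undershoot (an optional negative
kernel lobe could be added), vascular artifacts, eye movements during
widefield mapping, dendritic/axonal signal spread across area borders,
and spiking nonlinearities.  Passing the recovery tests therefore shows
the analysis chain is correct and self-consistent, not that these
real-data confounds are handled; on real data the validity floor, the
manual threshold range, and trial averaging carry that burden.

Problem sizes used throughout the tests and the acceptance script — a
96 × 96 atlas, two stimulus cycles, eight to forty synthetic cells at
ten sparse-noise repeats, a 40 × 40 × 12 tracer volume — were chosen as
the smallest sizes at which every recovery property is comfortably
resolved.

## Known limitations

- The one-pixel border tie-break is label-order dependent; mirrored
  inputs reproduce geometry only up to one pixel along borders.
- Internal-redundancy computation clusters contributing pixels per
  visual cell; for maps sampled much more coarsely than the coverage
  grid a cell rarely holds two pixels and redundancy is underestimated.
  Match `coverageResolutionDeg` to the cortical sampling density.
- The roughness-based $r$ estimator assumes the neuropil carries fast
  shared fluctuations; if the neuropil trace were as smooth as the soma
  the ratio would be weakly identified (a degenerate trace yields r = 0
  with a warning).
- Streamline surface projection uses orthographic top-view only; curved
  flattenings are out of scope.
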
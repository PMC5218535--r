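Package: retinomap
Title: Retinotopic Mapping and Visual Area Segmentation for Widefield
    Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for generating retinotopic maps of mouse cortex from
    periodic-stimulus widefield fluorescence movies: stimulus geometry with
    spherical correction, delta-F/F preprocessing, altitude and azimuth
    position maps from first-harmonic Fourier phase, visual field sign maps,
    automated segmentation of retinotopic patches with one-pixel borders,
    visual-coverage and eccentricity analysis, cross-animal map averaging by
    vector summation, infrared pupil and gaze tracking, single-cell
    receptive-field mapping with neuropil subtraction, and projection-based
    retinotopy from tracer volumes.  A synthetic-cortex simulator with known
    ground truth supports parameter-recovery validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'atlas.R'
    'stimulus.R'
    'cellrf.R'
    'fieldsign.R'
    'coverage.R'
    'fourier.R'
    'groupmaps.R'
    'io.R'
    'simulate-widefield.R'
    'pipeline.R'
    'projection.R'
    'pupil.R'
    'retinomap-package.R'
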
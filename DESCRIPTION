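Package: made
Title: Movement Artifact Direction Estimation from Single-Frame Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the direction (degrees) and weighted magnitude (pixels)
    of movement artifacts in a single grayscale frame. Implements a
    signal-processing pipeline that extracts scanlines along four principal
    directions, locates artifact replicas by prominence-filtered peaks of a
    normalized self-similarity profile (MAPE), anchors each scanline at its
    dominant intensity transition via exponential-moving-average slope
    analysis (ROPE), quantifies per-scanline displacements with plausibility
    suppression (MAQ), and fuses the four directional statistics through a
    3D octagon mapping with reliability weighting, adjacent-triplet
    selection, center-of-mass direction estimation and ray-polygon
    intersection (MADE). Includes a trajectory-based motion-blur simulator
    (oscillation plus linear drift integrated over the exposure) that
    generates ground-truthed synthetic frames, plus an evaluation harness
    for angular-error sweeps over orientation and velocity grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tools,
    methods,
    stats,
    utils,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'config.R'
    'directional-prep.R'
    'maq.R'
    'made-geometry.R'
    'rope.R'
    'mape.R'
    'estimate.R'
    'motion-sim.R'
    'evaluation.R'
    'io.R'
    'made-package.R'
RoxygenNote: 7.3.3
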
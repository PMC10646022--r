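Package: pccfm
Title: Photonic Crystal Cellular Force Microscopy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts color micrographs of deformable photonic-crystal
    substrates into per-pixel vertical displacement and vertical stress maps,
    and integrates vertically directed cell forces over regions and time.
    Implements the Bragg-condition optics linking reflection peak wavelength
    to substrate thickness, hue-to-wavelength calibration built from
    gradient-deformed wedge images, a hyperspectral reference branch for
    per-pixel peak wavelength mapping, linear-elastic inversion of wavelength
    shifts to vertical stress, region segmentation and force integration,
    and time-lapse analytics (velocity maps, total-force traces, beat
    detection, static/dynamic stress decomposition, drug-response
    classification, force-area regression). A seeded physics-based synthetic
    scene generator (reflectance spectra rendered through a camera model with
    spectral crosstalk, read noise and quantization) makes every stage
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    EBImage,
    igraph,
    zoo,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'optics.R'
    'synthetic.R'
    'calibration.R'
    'hyperspectral.R'
    'mechanics.R'
    'dynamics.R'
    'io.R'
    'pipeline.R'
    'cli.R'
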
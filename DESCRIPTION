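Package: mesomap
Title: Mesoscale Optical Intrinsic Signal Imaging Analysis of Mouse Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for wide-field optical intrinsic signal
    imaging (OISI) of the mouse dorsal cortex. Converts multi-wavelength
    reflectance movies to oxy-, deoxy- and total hemoglobin concentration
    changes via the modified Beer-Lambert law, preprocesses them (quality
    control, temporal resampling, band-pass filtering, global signal
    regression, landmark-based affine registration), and implements
    block-design evoked response mapping, seed-based resting-state
    functional connectivity, whole-cortex correlation matrices and node
    degree maps, spatial PCA of correlation difference matrices with
    permutation eigenvalue testing and data-driven ROI derivation,
    photostimulus effective-connectivity and inhibition indexing, and
    ancillary behavioral and qPCR expression metrics. A synthetic-cortex
    generator with known ground truth supports end-to-end validation and
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
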
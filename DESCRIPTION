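Package: oligoIMS
Title: Oligomer Order, Distribution and Shape from Native ESI-IM-MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for characterising amyloid-beta oligomers by
    native electrospray ion-mobility mass spectrometry (ESI-IM-MS).
    Computes theoretical ion grids for covalent (cross-linked) and
    non-covalent oligomers, assigns observed peaks from the 13C isotope
    spacing or from consecutive charge states, deconvolves ion-mobility
    mobilograms into a constant baseline plus Gaussian components
    parameterised by centre, width at half-height and area, derives
    charge-state-weighted oligomer population distributions with replicate
    statistics, calibrates traveling-wave drift times to collision
    cross-sections (CCS) through calibrant proteins and a corrected
    drift-time power law, and computes theoretical CCS from atomic
    coordinates by the projection approximation and the exact hard-sphere
    scattering method. A synthetic-data generator with recorded ground
    truth stands in for the instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
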
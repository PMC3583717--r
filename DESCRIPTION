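Package: rosettes
Title: Quantification of Rosette-Based Cell Internalization in Early C.
    elegans Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for time-lapse fluorescence recordings of
    C. elegans gastrulation, where internalizing cells are sealed over by
    multicellular rosettes formed from the centripetal extensions of their
    neighbours.  Provides line-profile and kymograph measurement of
    cortical myosin signals, detection and tracking of pulsatile
    contractile foci, time-lagged correlation of local contraction
    intensity with extension-tip advancement, a geometric model of
    circumferential tissue spreading under coplanar oriented divisions,
    migration-path smoothing and left/right movement-correlation matrices
    from lineage tracks, polygon-based morphometrics (axis ratios,
    covering fractions, bleb areas), and a seeded synthetic-data generator
    that emulates the statistical structure of the raw recordings so the
    whole pipeline can be exercised without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
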
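Package: planktonDVM
Title: Shadowgraph Imaging and Moonlight Models for Zooplankton Diel
    Vertical Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for
    high-resolution in situ studies of zooplankton diel vertical migration
    with a shadowgraph plankton imager. Provides a lunar/solar ephemeris and
    a simplified sky-brightness model for surface illuminance, Beer-Lambert
    attenuation of light into 10 cm depth bins with a scotopic detection
    floor, a synthetic-data generator that renders ground-truthed shadowgraph
    frames from gamma-distributed depth density fields, an image-processing
    chain (flat-fielding, binarization, ROI morphometry with equivalent
    spherical diameters, rule-based taxon classification), frame de-overlap
    and depth binning into density tables, and gamma log-link generalized
    linear mixed models with parametric-bootstrap highest-posterior-density
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    EBImage,
    glmmTMB,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
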
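Package: nanodomain
Title: Nanodomain Cluster Analysis for Single-Molecule Localization
    Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Point-pattern analysis of single-molecule localization
    microscopy (PALM/STORM) data aimed at membrane-protein nanodomains:
    blink-artifact correction (activation-cycle filtering, consecutive-frame
    merging, fiducial drift correction), two-stage DBSCAN clustering with the
    clustered-fraction readout, convex-hull cluster geometry with lognormal
    size-distribution fits, Gaussian cluster-mask verification of true
    clustering against the random-blinking reference curve
    rho/rho0 = 1 + 1.4*eta^4, fixed-radius nearest-neighbor density maps,
    and coordinate-based colocalization (CBC) for dual-color data.  A
    synthetic localization-data generator with full ground truth stands in
    for microscope data so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
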
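Package: scopeflow
Title: Resumable Two-Phase Slide Imaging Workflows with a Simulated Microscope
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, hardware-free framework for high-content slide
    imaging workflows. A virtual microscope renders synthetic slides carrying
    embryo-like textured objects, and a database-backed workflow engine drives
    a two-phase acquisition: a low-magnification tiled or live-view survey,
    object detection into stage-coordinate regions of interest, slide reload
    with pose re-calibration against the frosted-band edge, and
    high-magnification re-imaging with autofocus. Tiled acquisitions are
    assembled by phase-correlation stitching with translation-only global
    adjustment, and runs are summarised in self-contained HTML reports over a
    micro-manager-style dataset layout. Interrupted runs resume without
    repeating completed work.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
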
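Package: xrh
Title: 3D X-Ray Histology of Paraffin-Embedded Tissue Blocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for contrast-agent-free micro-computed-tomography (microCT)
    imaging of formalin-fixed paraffin-embedded (FFPE) tissue blocks integrated
    with conventional 2D histology. Provides the fixed preprocessing chain for
    reconstructed 32-bit volumes (3D median filter, per-slice unsharp mask,
    linear windowing to 16 bit), paraffin-wax phantom based gray-value
    calibration with air-zero offsetting and multi-scan stability reporting, 3D
    morphometry (maximal-inscribed-sphere local thickness, volume fraction,
    virtual/physical section-count arithmetic), rendering primitives (maximum
    intensity projections, multiplanar and oblique reslicing with bicubic
    interpolation), landmark-based coregistration of 2D histology slides with
    the 3D volume via thin-plate-spline elastic warping, and a synthetic
    phantom generator so the whole pipeline is testable without scanner data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    png,
    yaml,
    stats,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
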
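Package: bactrack
Title: Single-Bacterium Motility Tracking from Microscopy Frame Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated movement tracking of flagellated bacteria in
    phase-contrast video microscopy. Converts an ordered series of PNG
    frames into per-frame sum-difference images that suppress static
    content (debris in turbid media), detects moving particles and
    measures their morphological features, links detections across
    frames by optimal linear assignment on weighted feature differences
    with gap closing, and summarizes frame-to-frame velocities with
    rank-based statistics. Includes a synthetic scene generator with
    ground-truth tracks for validation without a microscope, a
    Hagen-Poiseuille capillary shear-stress calculator used to certify
    that sampling does not deflagellate cells, and optical-density
    dilution planning for sample preparation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    EBImage,
    nortest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
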
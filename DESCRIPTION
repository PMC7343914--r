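Package: speleoclean
Title: Virtual Cleaning and Morphometry of Matrix-Encased Skeletal Remains from CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to non-invasively "virtually clean" a skeletal specimen
    encased in speleothemic calcite from a clinical CT scan. Implements sparse
    manual contour segmentation with shape-based (signed-distance-field)
    inter-slice interpolation, masked erasure and series subtraction to isolate
    the specimen, threshold isosurface extraction with binary STL export,
    mesh-based osteometric measurement (proximal breadth, femoral-head depth,
    smallest shaft diameter), and multi-reader point-cloud congruence
    statistics. A synthetic bone-in-calcite phantom generator with analytic
    ground truth makes every stage testable without scan data, and an
    auxiliary module calibrates conventional radiocarbon ages against
    IntCal-format curves with highest-posterior-density ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RANN,
    Rcpp,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
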
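Package: rootCT
Title: Automated X-Ray CT Image Processing for 3-D Visualization of Root
    System Architecture
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fully automatic segmentation of plant root systems in
    reconstructed X-ray computed tomography volumes of soil-grown plants.
    Implements a mode-anchored grayscale normalization for scan-to-scan
    comparability, a 3-D median filter and per-slice blur-subtraction edge
    detection chain that isolates roots from a granular soil matrix,
    optional size-opening noise removal, cylindrical cropping, and 8-bit
    export of processed slice stacks. Includes a seeded synthetic phantom
    generator that emulates micro-CT volumes of fibrous root systems
    (partial-volume attenuation of sub-voxel roots, correlated soil noise,
    voids, cracks, pot wall) with ground truth, a detection-limit
    evaluator, contrast-to-noise and maximum-intensity-projection metrics,
    and scan-protocol arithmetic (scan time, field of view, X-ray dose
    budgets) for repeated 4-D imaging of the same plant.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Rcpp,
    jsonlite,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'ct_io.R'
    'normalize.R'
    'core.R'
    'metrics.R'
    'phantom.R'
    'evaluate.R'
    'protocol.R'
    'zzz.R'
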
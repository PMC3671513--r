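Package: wbcde
Title: White Blood Cell Detection by Differential-Evolution Ellipse Fitting
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects white blood cells (leukocytes) in blood-smear microscopy
    images by treating detection as a multi-ellipse optimization problem. A
    diffused expectation-maximization segmentation isolates the stained cells,
    a morphological operator extracts the edge map, and a differential
    evolution (best/1/bin) search over five-edge-point candidates finds the
    ellipses whose midpoint-algorithm rasterization best coincides with the
    edge pixels. Includes a seeded synthetic smear-image generator with
    ground-truth ellipses, salt-and-pepper and Gaussian corruption models,
    and detection-rate / false-alarm-rate evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
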
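Package: colonynet
Title: Colony-Level Social Networks and Repeatability Partitioning from
    Automated Detection Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds daily interaction (perch clumping, strict simple ratio
    index) and association (feeder co-occurrence, simple ratio index)
    networks from per-frame detection records of barcode-tagged birds,
    computes seven colony-level network metrics with a randomized
    smallest-edge-weight correction for disconnected networks, and
    partitions day-to-day variance in each metric into external drivers
    (group size, composition, weather, aviary, detection effort) versus
    consistent colony identity (repeatability), with bootstrap confidence
    intervals. Includes a synthetic detection-stream generator with known
    ground truth for validation, and a reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse
Config/testthat/edition: 3
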
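Package: blastograde
Title: Automated Quality Grading of Bovine Blastocyst Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive grading of in vitro produced bovine blastocysts from
    single-channel micrographs. Detects the embryo by a circular Hough
    transform, standardizes brightness and inner-cell-mass pose, partitions
    the embryo into zona/trophectoderm ring and inner compartments, and
    summarizes each image as a fixed 36-variable vector of circularity,
    intensity, gray-level co-occurrence texture and watershed-region
    statistics. A collinearity analysis reduces the vector to 24 neural
    network inputs and an island-model genetic algorithm evolves the
    feed-forward network that maps them to the three IETS quality grades
    (excellent/good, regular, poor), evaluated by exact agreement against an
    examiner-consensus template with an ordinal critical-error count. Includes
    a seeded synthetic-micrograph generator with simulated examiner panels
    for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
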
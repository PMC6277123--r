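Package: polyadapt
Title: Forward Simulation of Polygenic Adaptation to a Shifted Trait Optimum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-based forward-time simulation of a diploid
    quantitative trait controlled by unlinked QTL under stabilizing
    selection, adapting to an instantaneous optimum shift through truncation
    selection, with a heritable genomic background and configurable
    bottleneck-and-growth demography. Includes a demography-matched neutral
    null for classifying fixations as hard sweeps or sweeps from standing
    variation, summary statistics of the adaptation process, allele
    frequency by effect size genetic-architecture matrices, and
    random-forest parameter-importance analysis with cross-validated
    accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    randomForest,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
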
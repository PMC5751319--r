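Package: kdaselect
Title: Gaussian Kernel Discriminant Analysis with Reconstruction-Error
    Scale Selection for Protein Subcellular Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kernel discriminant analysis (KDA) with a Gaussian kernel for
    supervised dimension reduction of high-dimensional protein feature
    vectors, together with a fast method for choosing the kernel scale
    parameter: edge and internal samples are selected from the largest
    class by centroid distance and epsilon-neighborhood purity, and the
    scale maximizing the gap between their kernel reconstruction errors
    (relative to the internal-sample spread) is retained.  Includes
    PSI-BLAST PSSM parsing, PsePSSM (1000-dimensional) and PSSM-S
    (220-dimensional) feature encodings, k-nearest-neighbour
    classification with jackknife (leave-one-out) evaluation, per-class
    sensitivity, specificity and Matthews correlation, a grid-search
    baseline for the scale parameter, synthetic data generators, and a
    command-line interface covering the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
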
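Package: sketchbias
Type: Package
Title: Minimizer Sketches and the Bias of the Minimizer Jaccard Estimator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for minimizer (winnowing) sketches of DNA k-mer sequences
    and for quantifying the statistical bias of the Jaccard similarity
    estimated from minimizer sketches. Implements seeded k-mer hashing,
    sketch construction and the charged-window decomposition, the
    configuration-count approximation to the expected sketch intersection,
    an analytical bias estimate with error bounds, closed-form bounds for
    sparsely matched and periodically mutated sequence pairs, exact
    expectations by permutation enumeration on small instances, Monte-Carlo
    estimation over hash replicates, and synthetic duplicate-free
    sequence-pair generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    generics,
    readr,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
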
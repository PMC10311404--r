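Package: sweepcnn
Title: Genome Scans for Selective Sweeps with Convolutional Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and localizes hard selective sweeps from phased SNP data by
    classifying sliding windows of the haplotype matrix with a convolutional
    neural network trained on coalescent simulations. Windows of W segregating
    sites are rendered as grayscale images (ancestral/derived/other states),
    classified as "neutral" or "selection", and the per-window posteriors are
    averaged into a genome-wide selection profile from which the sweep location
    and extent are estimated. Includes a self-contained coalescent simulator
    (equilibrium, population bottlenecks, continent-island migration with a
    ghost population, recombination hotspots, and hard complete sweeps
    conditioned on a logistic allele-frequency trajectory) that reads and
    writes Hudson ms format, plus evaluation metrics (F1, true positive rate
    at a fixed false positive rate, sweep localization success rate and
    detection accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    Biostrings,
    optparse
Config/testthat/edition: 3
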
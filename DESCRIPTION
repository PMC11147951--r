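Package: nfscore
Title: Sequence-Intrinsic Nucleosome Formation Scores from DNA Shape Power Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies 147-bp DNA as nucleosomal or linker from the power
    spectral density of pentamer-derived DNA shape profiles (minor groove
    width, propeller twist, helix twist, roll), and applies the classifier
    genome-wide as sliding-window nucleosome formation (NF) score tracks at
    low (binary, 50-bp step) and high (per-bp vote fraction, 7-bp step)
    resolution. Also provides a multi-sample DNase hypersensitivity peak
    count score, strand-aware meta-profiles over genomic anchors,
    length-quantile stratification of interval sets, and seeded synthetic
    generators (labeled training sequences, toy genomes, pentamer tables,
    peak panels) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    randomForest,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
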
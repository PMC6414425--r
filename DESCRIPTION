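Package: rloopr
Title: R-Loop Gene Classification and Spike-In Normalized ChIP-seq
    Quantification at Polycomb Target Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the interplay between R-loops and Polycomb
    repression from genomics data: classification of genes as R-loop
    positive, negative, or uncertain-due-to-proximity from DRIP-seq peaks;
    exogenous (spike-in) normalization of ChIP-seq read counts with
    duplicate-read frequency thresholding; sense-strand nascent-RNA RPKM
    calls from stranded run-on coverage; TSS/TES meta-profiles in 10-bp
    bins with rank-based and t statistics; and percent-of-input qPCR
    quantification. Includes a fully seeded synthetic-data generator with
    planted gene classes, peaks, coverage, duplicated spike-in-mixed reads
    and Ct tables, so that every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
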
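Package: mirstm
Title: Behavioral Phenotyping and miRNA Expression Pipeline for Short-Term
    Memory Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline linking short-term-memory phenotypes of
    middle-aged mice to differential hippocampal miRNA expression.
    Implements scoring and Unimpaired/Impaired classification for the
    six-different-object recognition task (novel exploration versus
    familiar mean + k standard deviations), two-channel LNA microarray
    preprocessing from probe-level intensities to per-miRNA expression
    calls (flag removal, endogenous-control normalization, intensity
    windowing, fold-change/SD retention, replicate averaging, +/-0.7
    log2-ratio calling), relative quantification of qPCR Ct triplicates
    by the 2^-ddCt method with asymmetric error propagation,
    cross-platform Pearson agreement and candidate selection, consensus
    miRNA-target selection with descriptive interaction-network degree
    statistics, and seeded synthetic-data generators with known ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    igraph,
    jsonlite,
    stats,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
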
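Package: dielarray
Title: Diel Gene Expression Analysis for Targeted Microarray
    Metatranscriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing diel (24 h periodic) gene expression in
    targeted microarray metatranscriptomes of marine microbial populations,
    such as the nitrogen-fixing cyanobacterial symbiont UCYN-A. Covers the
    full pipeline: probe-level screening for cross-hybridization, quantile
    normalization and median-polish probe-set summarization,
    spike-in-calibrated gene detection with a signal-to-noise rule,
    Fourier-score periodicity calling against autoregressive background
    simulations with a ratio-based false discovery rate, peak-time and
    cross-habitat comparison statistics, and environmental covariate
    analysis (mixed-layer depth, NMDS ordination with permutation-tested
    environmental vectors). A synthetic-data module generates probe-level
    fixtures with known ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
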
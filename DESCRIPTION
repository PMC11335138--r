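Package: trackatlas
Title: Compilation and Analysis of Multi-Condition Cell Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles single-cell and single-particle tracking exports
    (TrackMate XML, TrackMate-style CSV, or generic CSV) from a
    Condition/Repeat directory tree into a unified spots + tracks table
    format, and analyses them end to end: track smoothing and filtering,
    motility metrics (directionality, tortuosity, speeds, turning angles,
    spatial coverage), replicate-aware statistics (Cohen's d, randomization
    tests, SuperPlots-style bootstrap t-tests, Bonferroni adjustment),
    dataset balance quality control with cosine-similarity dendrograms and
    balanced resampling, behavioural fingerprinting via UMAP/t-SNE embedding
    and HDBSCAN density clustering, and spatial analyses (Ripley's L with
    Monte-Carlo envelopes, distance-to-region-of-interest time series). A
    seeded synthetic track generator with known ground truth supports fully
    reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    xml2,
    jsonlite,
    yaml,
    ggplot2,
    uwot,
    Rtsne,
    FNN,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
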
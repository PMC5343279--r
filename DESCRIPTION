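Package: bindwave
Title: Consensus Transcription-Factor Binding Sites, Chromatin Context,
    E-Box Clusters, ChIP-qPCR Enrichment and Store-Operated Calcium Entry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream characterization of transcription-factor ChIP-Seq
    peaks and their functional follow-up assays. Derives high-confidence
    consensus binding sites from replicate peak calls, classifies peak
    midpoints against gene models (promoter, exonic, intronic, intergenic),
    scores peaks against chromatin-mark signal tracks, quantifies E-box
    (CANNTG) cluster enrichment and sliding-window conservation profiles,
    computes ChIP-qPCR percent-input and fold-enrichment statistics, and
    quantifies store-operated calcium entry (SOCE) from per-cell
    fluorescence traces. A seeded synthetic-data generator emulates every
    input with known ground truth so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    tools,
    utils,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
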
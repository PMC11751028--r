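Package: droplethic
Title: Droplet Single-Cell Hi-C Processing and Chromatin Architecture Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for droplet-based single-cell Hi-C: cell-barcode
    whitelist correction, barcode-aware contact deduplication, knee-point
    cell calling on barcode-rank curves with adaptive sensitivity,
    species-mixing (barnyard) doublet detection, per-cell A/B compartment
    (scA/B) scoring from CpG density of contact partners, pseudobulk and
    metacell contact-map aggregation with iterative-correction balancing,
    distance-decay curves, insulation scores and TAD boundary statistics,
    domain-melting scores, and metacell-level differential
    compartmentalization tests. Includes a fully seeded synthetic-data
    generator with ground-truth tables for every processing stage.
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
    stringr,
    rlang,
    generics,
    ggplot2,
    Matrix,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
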
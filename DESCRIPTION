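Package: elovlkit
Title: Functional Characterization Analytics for Elovl Fatty Acid Elongases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for heterologous-expression studies of Elovl
    elongases acting on very long-chain (>C24) fatty acids. Parses lipid
    shorthand nomenclature, builds +2-carbon elongation cascades and computes
    the step-wise conversion statistic from FAME gas-chromatography peak-area
    tables; compares very long-chain saturated fatty acid profiles between
    control and transgenic yeast with one-way ANOVA, Tukey HSD and compact
    letter displays; performs absolute qPCR quantification via plasmid
    standard curves with reference-gene normalization; scans deduced Elovl
    proteins for diagnostic motifs; and ships synthetic-data generators with
    known ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
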
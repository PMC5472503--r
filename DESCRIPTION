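Package: immunosig
Title: Immunosignature Peptide Microarray Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for immunosignature profiling on random-peptide microarrays:
    simulation of two-channel (IgG/IgM) array scans with a planted discriminative
    motif, GenePix-style spot-table input/output, the quality-control and
    normalization chain used for antibody-binding data (background subtraction,
    negative-incidence filtering, within-array median and between-array Aquantile
    normalization, replicate averaging, cohort missingness filtering), derivation
    of a minimal diagnostic peptide signature by progressive random-forest
    reduction with out-of-bag evaluation, BLAST traceback (btop) parsing with
    identity-run filtering and size-adjusted protein ranking, and conserved-motif
    consensus discovery across signature peptides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    methods,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
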
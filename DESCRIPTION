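Package: glutaquant
Title: Quantification and Differential Analysis of Protein
    S-Glutathionylation from ICAT Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Proteome-wide cysteine S-glutathionylation analysis from
    isotope-coded affinity tag (ICAT) heavy:light peptide ratio tables.
    Provides confidence and ratio filtering, technical-replicate collapse,
    per-group averaging, case/control ratio-of-ratios with Mann-Whitney
    significance testing, peptide-to-protein cysteine-site mapping,
    cross-condition overlap, hypergeometric over-representation analysis
    (including joint protein-metabolite pathway testing), and a
    synthetic-data generator with planted effects for benchmarking
    recovery of differential glutathionylation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
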
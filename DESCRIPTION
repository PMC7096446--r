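Package: chargescan
Title: Charged-Domain Scanning and Capsid-Genome Charge Balance for Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window net-charge analysis of protein sequences aimed at
    arginine-rich, positively charged domains (R-arms) of viral capsid
    proteins. Provides fixed-frame and variable-frame scanners for the most
    positively charged stretch of a protein, hypergeometric enrichment
    statistics of net-charge spectra with false-discovery-rate control,
    arginine/lysine composition profiling, and a robust (ROUT-style)
    linear-fit analysis of total capsid charge against genome charge with
    outlier detection. Includes seeded synthetic-data generators for
    proteomes with implanted charged domains and for capsid datasets with a
    known charge-balance relation, plus a command-line interface.
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
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
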
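Package: hetphos
Title: Kinase-Specific Phosphorylation Site Prediction from Heterogeneous
    Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts kinase-family-specific phosphorylation sites by
    integrating the peptide sequence and secondary-structure context of
    candidate serine/threonine residues with protein-level functional
    annotations such as pathways, ontology terms, domains and interaction
    partners.  Substrate-associated annotation terms are selected by
    two-sided hypergeometric tests under Bonferroni control, candidate
    proteins are prioritized with a redundancy-weighted log-odds score,
    and individual sites are classified with a radial-basis-function
    support vector machine evaluated by leakage-safe cross-validation.
    Includes a synthetic-data generator that plants sequence motifs and
    over/under-represented annotation terms so the whole pipeline can be
    exercised and calibrated without external databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
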
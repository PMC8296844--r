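Package: plastomics
Title: Comparative Plastome Analysis: Pseudogene Calling, Windowed
    Alignment Tracks, Per-Gene Rates and Selection Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of plastid (chloroplast)
    protein-coding genes across taxa: extraction of CDS features from
    GenBank flat files, translation-guided codon alignment, detection of
    pseudogenization lesions (frameshift, premature stop codon,
    truncating deletion) with a gene-by-taxon status matrix, 100-bp
    windowed GC/gap/parsimony-substitution tracks, per-gene evolutionary
    rate scalers on a pseudogene-masked concatenation under JC69,
    Nei-Gojobori Kn/Ks, two independent site-level selection tests
    (a counting test and an empirical-Bayes grid) with a two-method
    consensus rule, branch-level Kn/Ks screening, and ontology-level
    enrichment of selected sites by Fisher's exact test with
    Holm-Bonferroni adjustment. Includes a codon-model simulator that
    generates ground-truth datasets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
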
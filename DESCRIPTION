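Package: barcodeval
Title: Evaluation of Single- and Multi-Locus DNA Barcodes for Species
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate how well candidate DNA-barcode loci and their
    combinations discriminate closely related plant species. Implements
    Kimura two-parameter (K2P) pairwise distances with pairwise deletion,
    alignment characteristics (variable and parsimony-informative sites,
    indel events), global and local per-species barcoding-gap analysis,
    nearest-neighbour Best Match and Best Close Match identification with an
    intraspecific-distance threshold, neighbor-joining tree construction
    with nonparametric bootstrap and monophyly-based discrimination, and
    enumeration and concatenation of multi-locus barcode combinations.
    Includes a seeded simulator of multi-species, multi-individual,
    multi-locus aligned datasets with rate heterogeneity across loci,
    singleton species, indels and optional chloroplast capture, so the whole
    pipeline can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
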
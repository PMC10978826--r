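Package: BarcodeAudit
Title: Auditing DNA Barcode Reference Libraries Against a Taxonomic Catalogue
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing the completeness and diagnostic power of DNA
    barcode reference libraries (e.g. COI-5P or ITS2 collections for
    mosquitoes) against an authoritative taxonomic catalogue. The package
    curates specimen/sequence dumps from BOLD-style and GenBank-style
    sources through an ordered, auditable filter chain, computes taxonomic
    and geographic coverage statistics per country and biogeographic
    region, detects the per-species DNA barcode gap from all-vs-all
    pairwise identity searches with a built-in local aligner, and explains
    coverage and gap presence with binomial GLM/GLMM fits under all-subsets
    AIC model selection. A fully deterministic simulator generates
    catalogues, record tables and barcode sequences with known ground
    truth so every pipeline stage can be validated without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    lme4,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    glmmTMB,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'BarcodeAudit-package.R'
    'RcppExports.R'
    'catalogue.R'
    'coverage.R'
    'records.R'
    'curation.R'
    'gap.R'
    'simulate.R'
    'stats.R'
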
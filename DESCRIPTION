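Package: pharmscan
Title: Pharmacogenomic Association Scans from Genotypes and Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A population-scale pharmacogenomics analysis toolkit. Classifies
    putatively functional variants in candidate pharmacogenes (loss-of-function
    rules, missense calls, position-weight-matrix scans of promoter regions),
    derives adverse-drug-effect (ADE) phenotypes from electronic-health-record
    style diagnosis and self-report tables, builds drug-exposure cohorts from
    ATC-coded prescriptions, tests variant-drug-ADE associations with
    covariate-adjusted logistic models including conditional adjustment for
    known variants, refines and replicates hits with diagnostic-group
    phenotypes and sum-of-z meta-analysis, and validates copy number in
    segmental-duplication genes with a k-mer read-count proxy. A synthetic
    cohort generator with planted effects makes every stage testable without
    access-controlled biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    jsonlite,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
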
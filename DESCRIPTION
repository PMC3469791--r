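Package: ethdiff
Title: Ethnic-Differentiation Candidate-SNP Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for candidate-SNP association studies that prioritize
    variants by extreme inter-population allele-frequency differences.
    Implements multi-population frequency-panel QC, difference-category
    candidate selection with category-allocated Bonferroni thresholds,
    additive-model logistic association testing with principal-component
    stratification adjustment, conditional analysis and EM-based linkage
    disequilibrium estimation, fixed-effects inverse-variance meta-analysis
    with Cochran's Q, and a Hardy-Weinberg-based attribution model that
    converts a per-allele odds ratio and group allele frequencies into a
    predicted between-population disease incidence rate ratio. A seeded
    Balding-Nichols simulator generates multi-group frequency panels and
    case-control cohorts under a planted genotypic-relative-risk disease
    model so the whole workflow is testable without external cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    vcfR,
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
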
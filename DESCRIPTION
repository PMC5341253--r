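Package: prefld
Title: Trans-Ethnic GWAS Follow-Up with the Preferential LD Approach
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate causal variants around replicated GWAS
    hits using preferential linkage-disequilibrium (LD) tagging statistics
    computed from a phased variant catalog, tests variants by allelic-dosage
    logistic regression with covariate screening and conditional analysis,
    applies study-wide multiple-testing correction via the effective number
    of independent tests, and evaluates whether prioritized candidates beat
    the GWAS hit at each locus. Includes a founder-mosaic simulator of
    two-population haplotype panels with a planted causal variant, so the
    whole follow-up workflow can be exercised on synthetic case-control
    data with known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
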
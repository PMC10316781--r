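Package: panelomics
Title: Multi-Omic Functional Characterization of Disease Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing disease gene panels with functional
    genomic annotation: per-gene structural, repeat and conservation features
    computed by interval arithmetic over gene models; tissue- and cell-type
    expression specificity; expression-weighted cell-type enrichment with
    covariate-matched bootstraps; pairwise panel comparisons with FDR control;
    class-balanced recursive feature elimination and low-dimensional embedding;
    gene-based rare-variant burden testing with one-sided Fisher tests; and
    case/control comparison of short tandem repeat allele-size tails. A
    synthetic-data module generates all pipeline inputs with planted effects so
    every stage can be exercised and calibrated without access-controlled
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    rtracklayer,
    uwot
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
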
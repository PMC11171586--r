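Package: svcoseg
Title: Familial Co-Segregation Analysis of Structural Variants
Version: 0.1.0
Authors@R:
    person("svcoseg", "developers", email = "svcoseg@example.org", role = c("aut", "cre"))
Description: Prioritizes structural variants (deletions, duplications,
    insertions, inversions) that co-segregate with a phenotype in multiplex
    families. Reads per-family and control-cohort SV VCFs, clusters calls
    across samples by reciprocal overlap, tiers variants by control carrier
    frequency (absent / rare / uncommon / common), filters them against
    per-family segregation schemes, annotates genomic context against gene
    models, and attaches null co-segregation probabilities computed by exact
    Mendelian gene dropping on the pedigree, including single-family exonic
    P(obs) and Bonferroni-corrected multi-family P(obs) statistics. Ships a
    synthetic-cohort simulator with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    igraph,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    IRanges,
    GenomicRanges,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
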
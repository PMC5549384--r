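Package: ccvarscan
Title: Genetic Variation in Protein Charge Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects significant, disjoint positive and negative charge
    clusters in protein sequences, projects them through gene models to
    genomic coordinates, overlaps and classifies sequence variants by type,
    molecular consequence, clinical class and minor-allele-frequency bin,
    and computes variant-density and amino-acid exchange statistics. Ships a
    synthetic-data generator that plants clusters, gene architectures and
    variant mixtures with known ground truth so every stage of the pipeline
    can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
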
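Package: sRNAseeker
Title: Genome-Wide Bacterial sRNA Discovery, Quantification and Regulatory
    Network Inference from Coverage Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers bacterial small regulatory RNAs (sRNAs) from
    unstranded short-read coverage by iterative trim-and-remap exact
    alignment, coverage-threshold segmentation with cross-sample support,
    boundary refinement and location-based classification into intergenic
    (ncRNA), antisense (asRNA) and UTR-associated candidates. Quantifies
    sRNA expression as length-normalized coverage, tests differential
    expression between stress conditions with a negative-binomial exact
    test and Benjamini-Hochberg correction, ordinates the sRNA-by-sample
    matrix by correspondence analysis, and builds an sRNA-pathway
    regulatory network from ingested target predictions via free-energy,
    rank and expression-correlation filters followed by hypergeometric
    pathway enrichment. Ships a synthetic-study generator producing
    genomes, annotations, planted sRNAs, reads and target-prediction
    tables with known ground truth so every stage can be benchmarked at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
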
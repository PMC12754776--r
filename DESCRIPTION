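Package: g4prom
Title: G-Quadruplexes and Alternative Promoter Usage from NET-CAGE Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for studying the relationship between
    DNA G-quadruplex (G4) structures and alternative promoter usage.
    Implements G4Hunter-style run-length scoring and sliding-window
    extraction of candidate G4 regions from genomic sequence; strand-aware
    tag-cluster (promoter) calling from per-base CAGE transcription start
    site (CTSS) counts with TPM support filters; annotation of tag clusters
    against gene models with composition filtering; differential promoter
    usage testing between two conditions via TMM normalization and a
    negative-binomial quasi-likelihood relative-usage test; G4 association,
    enrichment, signal and relative-density statistics with directionality
    classification; a splice-junction-based promoter activity branch for
    G4-ligand treatment experiments; and a synthetic data generator that
    emits every input format the pipeline consumes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
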
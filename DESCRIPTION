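Package: h2aubDiff
Title: Differential H2Aub1 ChIP-Seq Analysis and Polycomb Mark Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coverage-scaled quantification of histone-mark ChIP-seq
    fragment libraries, M-A (MAnorm-style) differential enrichment
    between conditions with replicate-concordance filtering, definition
    of deubiquitinase (UBP12/13) target genes from H2Aub1 gain, per-gene
    H2Aub1/H3K27me3 categorization and PRC1-dependency classification,
    CTCTGYTY motif scanning and cluster detection with REF6 co-enrichment
    regression, and the associated statistical layer (hypergeometric
    overlap enrichment, Mann-Whitney tests, chi-square up/down asymmetry,
    ANCOVA estimated marginal means, Bonferroni correction). Includes a
    synthetic-data generator that emulates a complete miniature study
    with planted ground truth so every stage of the pipeline can be
    validated by parameter recovery.
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
    rtracklayer,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: ChIPSeq, Epigenetics, DifferentialPeakCalling, Coverage,
    SequenceMatching, GeneRegulation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
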
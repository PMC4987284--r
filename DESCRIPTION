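Package: SomaticTx
Title: Direct Transcriptional Consequences of Somatic Mutation from RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies the direct transcriptional consequences of
    somatic mutation in cancer RNA-seq. A seed-and-extend split-read mapper
    resolves junctions between non-adjacent expressed loci; a discordant-pair
    caller nominates gene fusions; a taxonomy engine arranges junctions into
    exon skips, exon reusages, alternative donors/acceptors, premature
    polyadenylation and fusion subclasses with reading-frame prediction. A
    hierarchical Bayesian Dirichlet-process mixture deconvolves tumor versus
    stromal transcription from allele-specific expression of heterozygous X
    chromosome SNPs, and a rank-based mixture estimator quantifies the excess
    of aberrant transcription attributable to genomic rearrangement across a
    cohort. A synthetic-fixture generator emulates every input the methods
    consume, with truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
biocViews: Transcriptomics, StructuralVariation, GeneFusionDetection,
    AlternativeSplicing, Bayesian, Software
RoxygenNote: 7.3.3
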
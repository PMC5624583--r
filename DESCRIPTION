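Package: absquant
Title: Absolute-Scale qPCR Normalization and Count-Based Differential
    Expression for Somatic Embryogenesis Induction Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for expression analysis of explant induction time
    courses quantified by absolute qPCR (molecules per 10 ng total RNA)
    and bulk RNA-seq. Computes sample-specific normalization factors from
    reference-gene quantities so that technical sample-preparation
    scaling is removed without losing absolute units, builds normalized
    time-course expression profiles and classifies genes as
    responsiveness- or genotype-associated, and provides a post-mapping
    differential-expression stage: RPKM, moment-based tagwise
    negative-binomial dispersion, a conditional two-group exact test,
    Benjamini-Hochberg FDR, a directional fold-change filter, and
    per-day summary tables. A synthetic-data generator emulates the
    study designs (technical scaling, reference genes, flat /
    late-induced / early-transient target profiles, negative-binomial
    counts with planted fold changes) so every stage is verifiable by
    parameter recovery. Utilities cover positional FASTQ read trimming,
    contig length filtering, and a genomic-DNA contamination check.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    SummarizedExperiment,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
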
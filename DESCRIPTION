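Package: HaploDiverge
Title: Haplotig Purging and Inter-Haplotype Divergence for Heterozygous
    Diploid Assemblies
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for cleaning and comparing haplotype assemblies of
    highly heterozygous diploid genomes. Pairs allelic contigs using three
    evidence channels (all-by-all alignment coverage, micro-synteny
    collinear gene blocks, and shared single-copy completeness markers)
    and purges haplotigs of longer contigs; extracts SNPs, small INDELs
    (< 50 bp) and large presence/absence variants (>= 50 bp) from
    whole-genome alignment CIGARs; intersects them with a read-based
    callset under exact-start and slack-window concordance rules; and
    computes windowed sequence identity between haplotypes. Ships a
    truth-labelled heterozygous diploid genome simulator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: GenomeAssembly, SequenceMatching, StructuralVariation,
    Alignment, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
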
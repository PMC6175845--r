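Package: ProteinHaplotypes
Title: Protein and CDS Haplotype Reconstruction from Phased Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs per-individual, per-phase coding (CDS) and protein
    haplotypes from phased VCF genotypes, a reference genome and transcript
    models. Variants overlapping a transcript are projected into spliced CDS
    coordinates, applied 3'-to-5' to the reference coding sequence and
    translated in silico. Each haplotype is globally re-aligned to its
    reference to extract contiguous difference blocks which are rendered in a
    compact HGVS-like notation (e.g. 299D>G,399T>I). Haplotypes are aggregated
    across samples into per-population frequency-of-occurrence (FoO) tables,
    diplotype tallies and gene-complexity summaries. Includes a synthetic-data
    module generating toy genomes, transcript models and phased population
    VCFs with known ground truth, plus an independently implemented
    whole-genome editing oracle used to validate the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
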
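Package: ClonalSubs
Title: Substitution Accumulation and dN/dS Inference in Obligately Asexual
    Diploid Lineages
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for within-lineage molecular-evolution analysis of
    obligately parthenogenetic diploid lineages. Provides per-genotype
    substitution-rate estimation from diploid variant calls, codon-aware
    classification of coding changes, pairwise synonymous / nonsynonymous /
    non-coding substitution counting with homozygous-heterozygous sorting,
    pooled-resampling randomization tests for differences in regression
    slopes and locations between lineages, unique-nonsynonymous-gene
    tallies, and lineage dating from per-generation mutation rates. A
    synthetic clonal-lineage simulator (reference genome with gene models,
    star-topology mutation accumulation under tunable purifying selection)
    makes the whole pipeline testable without sequencing data.
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
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Genetics, SNP, Software
RoxygenNote: 7.3.3
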
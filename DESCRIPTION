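Package: rnaPopGen
Title: Population Genomics and Molecular Evolution from RNA-seq Base Counts
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for population-transcriptomic analysis of
    closely related, hybridizing species. Calls biallelic SNP genotypes from
    per-site, per-individual base counts with heterozygosity and missingness
    filters; computes per-SNP Weir-Cockerham FST, per-gene nucleotide
    diversity (pi) and Watterson's theta, and the Evanno deltaK statistic;
    detects open-ended reading frames, builds per-species consensus coding
    sequences and estimates dN/dS by Nei-Gojobori counting with Jukes-Cantor
    correction; performs McDonald-Kreitman tests in which substitutions are
    SNPs above an FST threshold, with G-tests, alpha estimation, bootstrap
    confidence intervals and GO-category scans; derives expression level,
    divergence and tissue-specificity metrics; and relates protein evolution
    to its genomic correlates through partial correlations. A seeded
    synthetic-data generator reproduces the statistical structure of each
    input so the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    VariantAnnotation,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SNP, Genetics, PopulationGenetics, Transcriptomics, Sequencing
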
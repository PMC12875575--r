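Package: TEforge
Title: Simulation and Benchmarking of Transposable Element Variants
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates polymorphic transposable element (TE) insertions and
    deletions across many samples. TE insertion sequences are derived from
    consensus libraries (with SNPs, INDELs, 5' truncation and 3' polyA tails
    under a configurable mutation model), from real insertion catalogs, or
    from simple bubbles of a pangenome graph. Variant-containing haplotype
    genomes are assembled with a chunk-merge block strategy and emitted as
    FASTA plus a multi-sample VCF; native short- and long-read simulators
    produce FASTQ at requested depths; and a comparison module matches
    predicted TE calls against the simulated truth under a positional
    tolerance, reporting sensitivity, precision, F1 and genotype concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
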
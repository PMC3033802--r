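Package: dafscan
Title: Detecting Purifying Selection from Derived Allele Frequency Spectra of SNP Classes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classifies single nucleotide polymorphisms into annotation-derived
    genomic classes (promoters, splice control regions, coding sequence,
    evolutionarily constrained elements, regulatory attributes), polarizes
    alleles against primate outgroups to obtain derived allele frequencies
    (DAF), and tests each class's DAF spectrum for an excess of low-frequency
    derived alleles -- the signature of negative (purifying) selection --
    against genome-wide and ancestral-repeat backgrounds using Mann-Whitney
    rank tests with Benjamini-Hochberg false discovery rate control. A
    matched-region permutation null controls for hitchhiking and background
    selection, and a synthetic-data generator produces complete input bundles
    with tunable selection intensity so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite,
    stats,
    graphics,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
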
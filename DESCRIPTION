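Package: fluctspec
Title: Fluctuation-Assay Mutation Rates and Mutation-Spectrum Analysis in Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting natural mutator phenotypes in budding yeast.
    Estimates loss-of-function mutation rates from Luria-Delbruck fluctuation
    assays by maximum likelihood under the Lea-Coulson model, calls mutations
    and multinucleotide mutation events from pooled-mutant amplicon pileups,
    builds strand-collapsed mutation spectra from panel polymorphisms
    polarized against an outgroup (with spectrum PCA and C>A enrichment
    scans), and compares spectra with a Monte-Carlo exact test on
    margin-fixed contingency tables. A synthetic-data generator provides
    fluctuation experiments, pooled pileups and polymorphism panels with
    known ground truth so that every pipeline stage is testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
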
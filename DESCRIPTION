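Package: meioscan
Title: Mapping Meiotic Crossovers from Low-Coverage Sequencing of Sibling Embryos
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects meiotic crossovers from very low-coverage (<0.05x per
    homolog) whole-genome sequencing of sibling embryos, as produced by
    preimplantation genetic testing for aneuploidy (PGT-A). A monosomic (or
    haploid) sibling chromosome is phased by default and serves as a
    reference haplotype; in adaptive genomic windows the method tests
    whether a disomic sibling matches that haplotype, using linkage
    disequilibrium from an external phased reference panel to compare
    matched versus unmatched haplotype hypotheses via a log-likelihood
    ratio. Per-window uncertainty is quantified by an m-out-of-n bootstrap,
    crossovers are called from local extrema of the cumulative
    log-likelihood track, and calls are attributed to the shared reference
    or to individual test embryos by cross-sibling clustering. Includes a
    synthetic phased-panel and read simulator for benchmarking, balanced
    ROC evaluation for the trinomial classifier, and downstream analyses of
    trisomy meiotic origin (BPH/SPH decision tree) and crossover-landscape
    comparison via eCDFs with a permutation Kolmogorov-Smirnov test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vcfR,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Genetics, SNP, Sequencing, StatisticalMethod, Coverage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
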
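Package: sweepmode
Title: Detection of Selective Sweeps and Inference of the Mode of Convergent
    Adaptation Across Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the repeated evolution of an adaptive phenotype
    (such as herbicide resistance) across replicate populations from SNP
    genotype data. Provides windowed diversity and differentiation statistics
    (nucleotide diversity, Tajima's D, Fay and Wu's H, Nei's G_ST,
    Weir-Cockerham F_ST, composite linkage disequilibrium), an empirical
    outlier scan for phenotype-associated SNPs with a randomized-grouping
    null, delimitation of outlier-enriched genomic regions, gene-family
    enrichment by genome resampling, haplotype-group assignment via classical
    multidimensional scaling and k-means, and a composite-likelihood test that
    discriminates between independent mutation, migration, and standing
    variation as the source of convergent sweeps, using a coancestry matrix to
    model neutral allele-frequency covariance among populations. A seeded
    multi-population genotype simulator with injected sweeps of each mode
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    GenomeInfoDb,
    vcfR,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
biocViews: PopulationGenetics, SNP, Genetics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
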
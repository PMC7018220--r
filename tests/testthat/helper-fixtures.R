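# shared fixtures: tiny genotype builders and the bundled panel

table1Path <- system.file("extdata", "populations.tsv",
                          package = "sweepmode")

table1Panel <- function() readPanel(table1Path)

# genotype container from an explicit dosage matrix (sites x samples),
# one population per sample prefix
tinyGenotypes <- function(g, pos = seq_len(nrow(g)) * 100L,
                          chrom = "chr1", populations = NULL,
                          ancestral = "A") {
    g <- as.matrix(g)
    if (is.null(colnames(g)))
        colnames(g) <- paste0("p", rep(seq_len(max(1, ncol(g) %/% 2)),
                              each = 2), "_",
                              rep(1:2, length.out = ncol(g)))
    if (is.null(populations))
        populations <- sub("_[0-9]+$", "", colnames(g))
    GenotypeData(g, chrom = rep_len(chrom, nrow(g)), pos = pos,
        ref = rep("A", nrow(g)), alt = rep("T", nrow(g)),
        ancestral = ancestral, samples = colnames(g),
        populations = populations)
}

# two-class panel over arbitrary populations
tinyPanel <- function(pops, rPops) {
    suppressWarnings(PopulationPanel(pops,
        ifelse(pops %in% rPops, 0.9, 0.1), "P"))
}

# a small eight-population scenario-like panel
eightPanel <- function() {
    suppressWarnings(PopulationPanel(names(scenarioPopulations()),
        scenarioPopulations(), "P"))
}

# cached default scenario: built once per test run, reused by the
# acceptance blocks (deterministic given the seed)
scenarioCache <- local({
    cache <- NULL
    function(seed = 1) {
        if (is.null(cache) || cache$truth$seed != seed)
            cache <<- makeDefaultScenario(seed = seed)
        cache
    }
})
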
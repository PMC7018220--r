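#' GenotypeData: diploid dosage matrix with site and sample metadata
#'
#' Container for biallelic SNP genotypes, stored as a
#' \linkS4class{RangedSummarizedExperiment} with a single \code{"dosage"}
#' assay (sites x samples, alternate-allele dosage in \{0, 1, 2\} or
#' \code{NA}). Row ranges carry \code{ref}, \code{alt} and optional
#' \code{ancestral} alleles; column data carry the sample-to-population map.
#' Sites are kept sorted by (chromosome, position) and the class validity
#' enforces the dosage domain.
#'
#' @slot .. see \linkS4class{RangedSummarizedExperiment}
#' @exportClass GenotypeData
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
    msg <- character()
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        g <- SummarizedExperiment::assay(object, "dosage")
        bad <- g[!is.na(g)]
        if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
            msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    need <- c("ref", "alt")
    if (!all(need %in% colnames(S4Vectors::mcols(rr))))
        msg <- c(msg, "rowRanges must carry 'ref' and 'alt' alleles")
    if (!"population" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must carry a 'population' column")
    if (length(rr) > 1L) {
        o <- order(as.character(GenomicRanges::seqnames(rr)),
                   GenomicRanges::start(rr))
        if (!identical(o, seq_along(rr)))
            msg <- c(msg, "sites must be sorted by (chrom, pos)")
    }
    if (length(msg)) msg else TRUE
})

#' PopulationPanel: per-population phenotype and usage metadata
#'
#' Mirrors a study's population panel table: population identifier, the
#' proportion of individuals surviving the selective agent (in [0, 1]),
#' and usage flags (which parts of a study the population enters, e.g.
#' \code{"E"} for candidate-gene sequencing, \code{"P"} for population
#' genomics). The resistance class is derived, not stored: survival above
#' 0.5 classifies a population as \code{"R"}, at or below 0.5 as \code{"S"}
#' (a panel listing survival exactly 0.5 as susceptible fixes the tie rule).
#'
#' @slot pop character, population identifiers (unique)
#' @slot survival numeric in [0, 1]
#' @slot usage list of character vectors of usage flags
#' @slot nSamples integer, genotyped samples per population (NA if unknown)
#' @exportClass PopulationPanel
setClass("PopulationPanel",
    representation(pop = "character", survival = "numeric",
                   usage = "list", nSamples = "integer"))

setValidity("PopulationPanel", function(object) {
    msg <- character()
    n <- length(object@pop)
    if (anyDuplicated(object@pop))
        msg <- c(msg, "population ids must be unique")
    if (length(object@survival) != n || length(object@usage) != n ||
        length(object@nSamples) != n)
        msg <- c(msg, "slot lengths differ")
    if (any(object@survival < 0 | object@survival > 1, na.rm = TRUE))
        msg <- c(msg, "survival must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' CoancestryMatrix: neutral allele-frequency covariance among populations
#'
#' A K x K symmetric matrix F such that, at a site with ancestral frequency
#' eps, the population allele-frequency vector is modelled as multivariate
#' normal with mean eps and covariance eps * (1 - eps) * F. Diagonal entries
#' lie in [0, 1]; the matrix is positive semi-definite after a small
#' eigenvalue clip. Off-diagonal entries of an estimated (mean-centred) F
#' may be slightly negative; that is expected and allowed.
#'
#' @slot mat numeric matrix with population dimnames
#' @exportClass CoancestryMatrix
setClass("CoancestryMatrix", representation(mat = "matrix"))

setValidity("CoancestryMatrix", function(object) {
    m <- object@mat
    msg <- character()
    if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
    else {
        if (max(abs(m - t(m))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
        if (any(diag(m) < -1e-8 | diag(m) > 1 + 1e-8))
            msg <- c(msg, "diagonal must lie in [0, 1]")
        ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < -1e-6)
            msg <- c(msg, "matrix must be positive semi-definite (after clipping)")
    }
    if (length(msg)) msg else TRUE
})

#' SweepModelParams: parameter bundle for a convergence sweep model
#'
#' Parameters of the hitchhiking models used both to inject sweeps into
#' simulated data and to score models by composite likelihood:
#' \code{model} is one of \code{"neutral"}, \code{"independent"},
#' \code{"migration"}, \code{"standing"}; \code{s} the selection
#' coefficient; \code{g} the standing frequency; \code{t} the standing time
#' in generations; \code{m} the migration rate; \code{source} the source
#' population (migration only); \code{Ne} the effective population size;
#' \code{r} the per-bp per-generation recombination rate; \code{x0} the
#' selected-site position; \code{selectedPops} the populations under
#' selection; \code{splitTime} the population split time (a context
#' constant, generations).
#'
#' @exportClass SweepModelParams
setClass("SweepModelParams",
    representation(model = "character", s = "numeric", g = "numeric",
                   t = "numeric", m = "numeric", source = "character",
                   Ne = "numeric", r = "numeric", x0 = "numeric",
                   selectedPops = "character", splitTime = "numeric"))

setValidity("SweepModelParams", function(object) {
    msg <- character()
    if (!object@model %in% c("neutral", "independent", "migration", "standing"))
        msg <- c(msg, "unknown model")
    if (object@model != "neutral") {
        if (!(object@s > 0 && object@s <= 1)) msg <- c(msg, "s must lie in (0, 1]")
        if (!(object@Ne > 0)) msg <- c(msg, "Ne must be positive")
        if (!(object@r > 0)) msg <- c(msg, "r must be positive")
    }
    if (object@model == "standing") {
        if (!(object@g > 0 && object@g < 1)) msg <- c(msg, "g must lie in (0, 1)")
        if (object@t < 0) msg <- c(msg, "t must be >= 0")
    }
    if (object@model == "migration" && !(object@m > 0 && object@m <= 1))
        msg <- c(msg, "m must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' RegionSet: outlier-delimited genomic regions
#'
#' Genomic intervals delimited from outlier SNP positions. Each region spans
#' the first to the last member outlier and carries the member count; the
#' provenance parameters (maximum within-region gap, minimum outlier count)
#' are kept alongside.
#'
#' @slot regions GRanges with mcols \code{regionId} and \code{nOutliers}
#' @slot params list of delimitation parameters
#' @exportClass RegionSet
setClass("RegionSet", representation(regions = "GRanges", params = "list"))

setValidity("RegionSet", function(object) {
    gr <- object@regions
    msg <- character()
    if (length(gr)) {
        if (!all(c("regionId", "nOutliers") %in% colnames(S4Vectors::mcols(gr))))
            msg <- c(msg, "regions must carry regionId and nOutliers")
        red <- GenomicRanges::reduce(gr)
        if (length(red) < length(gr))
            msg <- c(msg, "regions must be non-overlapping within chromosomes")
    }
    if (length(msg)) msg else TRUE
})

#' ConvergenceFit: composite-likelihood fit of one sweep model
#'
#' Result of a grid search for one model: the maximum composite
#' log-likelihood ratio versus the neutral model, the parameters and
#' selected-site position attaining it, and a per-candidate-position profile
#' (maximised over the parameter grid).
#'
#' @slot model character, model name
#' @slot maxRatio numeric, maximum composite log-likelihood ratio vs neutral
#' @slot mle list of parameter values at the maximum (includes x0)
#' @slot profile data.frame with columns \code{pos} and \code{ratio}
#' @slot grid data.frame of all evaluated (parameters, position, ratio)
#' @exportClass ConvergenceFit
setClass("ConvergenceFit",
    representation(model = "character", maxRatio = "numeric", mle = "list",
                   profile = "data.frame", grid = "data.frame"))
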
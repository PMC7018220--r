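#' Simulate a single sweep region for model-recovery studies
#'
#' Generates one candidate region under a chosen convergence mode at the
#' package's strong-signal settings: eight populations with the default
#' coancestry structure, a selected site at the centre of the region, and
#' diploid genotype sampling. Returns the sample allele frequencies (what
#' the likelihood machinery consumes) together with the truth bundle.
#'
#' @param model "independent", "migration" or "standing"
#' @param seed integer seed
#' @param nSnps SNPs in the region (default 200)
#' @param span region width in bp (default 4e6, selected site at centre)
#' @param nPerPop diploid individuals per population (default 10)
#' @param s,g,t,m sweep parameters (defaults: s = 1; standing g = 1e-2,
#'   t = 1000; migration m = 1 from WG)
#' @param source migration source population
#' @param draw sweep draw scheme (see \code{\link{injectSweep}})
#' @param nNeutral neutral sites simulated alongside for coancestry
#'   estimation (default 3000)
#' @return list with \code{freqs} (sample frequencies), \code{positions},
#'   \code{x0}, \code{nk}, \code{Fhat} (estimated from the neutral
#'   companion sites), \code{params}
#' @export
simulateSweepRegion <- function(model, seed = 1, nSnps = 200, span = 4e6,
        nPerPop = 10, s = 1, g = 1e-2, t = 1000, m = 1, source = "WG",
        draw = "haplotype", nNeutral = 3000) {
    Fm <- defaultCoancestry()
    pops <- populations(Fm)
    surv <- scenarioPopulations()
    selPops <- names(surv)[surv > 0.5]
    x0 <- span / 2
    params <- sweepParams(model, s = s, g = g, t = t, m = m,
        source = if (model == "migration") source else character(),
        x0 = x0, selectedPops = selPops)
    set.seed(seed)
    positions <- sort(sample.int(span, nSnps))
    sim <- simulateNeutralFreqs(Fm, nSnps, seed = seed + 1L)
    freqs <- injectSweep(sim$freqs, sim$eps, positions, params, Fm,
                         seed = seed + 2L, draw = draw)
    gd <- freqsToGenotypes(freqs, positions, "regionA",
                           nPerPop = nPerPop, seed = seed + 3L)
    if (draw == "haplotype" && !is.null(attr(freqs, "sweep")))
        gd <- GenotypeData(
            .sweepMosaicDosages(dosage(gd), positions, params,
                attr(freqs, "sweep"), samplePops(gd), seed = seed + 4L),
            chrom = rep("regionA", nSnps), pos = positions,
            ref = rep("A", nSnps), alt = rep("T", nSnps),
            ancestral = rep("A", nSnps), samples = colnames(gd),
            populations = unname(samplePops(gd)))
    neutral <- simulateNeutralFreqs(Fm, nNeutral, seed = seed + 5L)
    neutralGd <- freqsToGenotypes(neutral$freqs,
        sort(sample.int(1e8, nNeutral)), "neutralA", nPerPop = nPerPop,
        seed = seed + 6L)
    nk <- table(samplePops(gd))
    nk <- setNames(as.numeric(nk), names(nk))
    list(freqs = popAlleleFreqs(gd), positions = positions, x0 = x0,
         nk = nk, Fhat = estimateF(popAlleleFreqs(neutralGd)),
         params = params, genotypes = gd, trueF = Fm,
         selectedPops = selPops)
}

#' Reduced parameter grids for desk-scale convergence runs
#'
#' A coarser grid than \code{\link{defaultGrids}} that brackets the
#' strong-signal simulation settings; used by the packaged recovery
#' studies to keep runtimes in minutes.
#'
#' @return named list of grids
#' @export
reducedGrids <- function() {
    list(s = c(0.3, 0.5, 0.65, 0.8, 1), g = c(1e-6, 1e-4, 1e-2),
         t = c(0, 100, 1000, 10000), m = c(1e-4, 1e-2, 1))
}

#' Convergence-mode recovery study
#'
#' Simulates \code{nRep} regions per requested mode at strong-signal
#' settings, runs the composite-likelihood grid search on each, and
#' reports which model ranks first plus the recovered parameters. The
#' headline number is the fraction of replicates in which the generating
#' model attains the highest maximum composite log-likelihood ratio.
#'
#' @param models modes to simulate
#' @param nRep replicates per mode (default 20)
#' @param seed integer seed
#
#' @param stride candidate-position stride (default 10)
#' @param draw sweep draw scheme; the default "gaussian" draw matches the
#'   likelihood's own distribution, making this a self-consistency study
#' @param m migration rate for the migration-mode simulations. The default
#'   1e-4 keeps the migration corner identifiable: at m = 1 the migration
#'   process coincides exactly with standing variation at t = 0 and model
#'   ranking between the two is a coin toss; a low rate makes the
#'   source/recipient decay asymmetry informative
#' @param nPerPop diploid individuals per population (default 50; the
#'   sampling-noise term must be small relative to the drift covariance
#'   for the mode differences to be visible)
#' @param s selection coefficient for every simulated mode (default 1)
#' @param g standing frequency for the standing-mode simulations (default
#'   1e-2: a broad sweep footprint that no other model can imitate, which
#'   keeps the standing corner identifiable)
#' @param ... further arguments to \code{\link{simulateSweepRegion}}
#' @return data.frame with one row per replicate: mode, bestModel,
#'   recovered s and x0, and the per-model max ratios
#' @export
modeRecoveryStudy <- function(models = c("independent", "migration",
        "standing"), nRep = 20, seed = 1, grids = reducedGrids(),
        stride = 10, draw = "gaussian", s = 1, m = 1e-4, g = 1e-2,
        nPerPop = 50, ...) {
    rows <- list()
    for (mode in models) {
        for (rep in seq_len(nRep)) {
            repSeed <- (seed * 1000L + match(mode, models) * 100L +
                        rep) %% .Machine$integer.max
            sim <- simulateSweepRegion(mode, seed = repSeed, draw = draw,
                                       s = s, m = m, g = g,
                                       nPerPop = nPerPop, ...)
            fits <- convergenceGridSearch(sim$freqs, sim$positions,
                sim$Fhat, sim$nk, sim$selectedPops, grids = grids,
                stride = stride)
            best <- fits[[1]]
            rows[[length(rows) + 1L]] <- data.frame(mode = mode,
                rep = rep, bestModel = best@model,
                sHat = best@mle$s, x0Hat = best@mle$x0,
                ratioIndependent = fits[["independent"]]@maxRatio,
                ratioMigration = fits[["migration"]]@maxRatio,
                ratioStanding = fits[["standing"]]@maxRatio)
        }
    }
    do.call(rbind, rows)
}
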
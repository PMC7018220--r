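selPops <- c("WG", "BI", "DW", "SPC")

test_that("hitchhiking probability follows its closed form", {
    p <- sweepParams("independent", s = 1, r = 1e-8,
                     selectedPops = selPops)
    expect_equal(sweepY(0, p), 1)
    expect_lt(sweepY(1e9, p), 1e-6)
    # direct calculator check: Ne = 7.5e5, s = 1, r = 1e-8, d = 1e5
    expect_equal(sweepY(1e5, p), exp(-1e-3 * log(1.5e6)))
    # standing model uses p0 = g
    ps <- sweepParams("standing", s = 0.5, g = 1e-4, r = 1e-8,
                      selectedPops = selPops)
    expect_equal(sweepY(2e5, ps), exp(-1e-8 * 2e5 * log(1e4) / 0.5))
    # monotone: decreasing in d, increasing in s
    d <- seq(0, 1e7, length.out = 50)
    expect_true(all(diff(sweepY(d, p)) < 0))
    p2 <- sweepParams("independent", s = 0.5, r = 1e-8,
                      selectedPops = selPops)
    expect_true(all(sweepY(d[-1], p) > sweepY(d[-1], p2)))
})

test_that("model covariances collapse to neutral far away and nest correctly", {
    Fm <- coancestry(defaultCoancestry())
    for (model in c("independent", "migration", "standing")) {
        p <- sweepParams(model, s = 1, g = 1e-3, t = 100, m = 0.5,
            source = "WG", x0 = 0, selectedPops = selPops)
        far <- modelCovariance(Fm, 1e10, p)$Fp
        expect_equal(far, Fm, tolerance = 1e-9)
    }
    # standing at t = 0 with g = 1/(2 Ne) coincides with migration at
    # delta = 0 (m = 1): P_coal = 0, P_through = 1
    Ne <- 7.5e5
    pst <- sweepParams("standing", s = 1, g = 1 / (2 * Ne), t = 0,
                       Ne = Ne, selectedPops = selPops)
    pmi <- sweepParams("migration", s = 1, m = 1, source = "WG", Ne = Ne,
                       selectedPops = selPops)
    for (d in c(0, 1e4, 1e6))
        expect_equal(modelCovariance(Fm, d, pst)$Fp,
                     modelCovariance(Fm, d, pmi)$Fp, tolerance = 1e-12)
    # standing t -> infinity: cross-population entries revert to neutral,
    # within-population keeps the K_s/(K_s + 2 r d) weighting
    pInf <- sweepParams("standing", s = 1, g = 1e-4, t = 1e7,
                        selectedPops = selPops)
    d <- 1e5
    FpInf <- modelCovariance(Fm, d, pInf)$Fp
    expect_equal(FpInf["WG", "BI"], Fm["WG", "BI"], tolerance = 1e-9)
    Ks <- 1 / (2 * 7.5e5 * 1e-4)
    y2 <- sweepY(d, pInf)^2
    w <- y2 * Ks / (Ks + 2 * pInf@r * d)
    expect_equal(FpInf["WG", "WG"], w + (1 - w) * Fm["WG", "WG"],
                 tolerance = 1e-9)
    # monotonicity: the between-selected term decreases in t and d
    bt <- vapply(c(0, 10, 100, 1000), function(tv)
        modelCovariance(Fm, 1e4, sweepParams("standing", s = 1, g = 1e-4,
            t = tv, selectedPops = selPops))$Fp["WG", "BI"], 0)
    expect_true(all(diff(bt) < 0))
    bd <- vapply(c(0, 1e4, 1e5, 1e6), function(dv)
        modelCovariance(Fm, dv, sweepParams("standing", s = 1, g = 1e-4,
            t = 100, selectedPops = selPops))$Fp["WG", "BI"], 0)
    expect_true(all(diff(bd) < 0))
})

test_that("composite log-likelihood matches a brute-force MVN evaluation", {
    Fm <- coancestry(defaultCoancestry())
    nk <- setNames(rep(10, 8), rownames(Fm))
    set.seed(52)
    sim <- simulateNeutralFreqs(Fm, 5, seed = 53)
    pos <- sort(sample.int(2e6, 5))
    P <- sweepmode:::.projMatrix(8)
    for (model in c("neutral", "independent", "migration", "standing")) {
        p <- sweepParams(model, s = 0.8, g = 1e-3, t = 500, m = 0.1,
            source = "WG", x0 = 1e6, selectedPops = selPops)
        got <- compositeLoglik(sim$freqs, pos, 1e6, p, Fm, nk)
        x <- pmin(pmax(sim$freqs, 0.01), 0.99)
        eps <- colMeans(x)
        want <- 0
        for (i in 1:5) {
            Fp <- if (model == "neutral") Fm else
                modelCovariance(Fm, abs(pos[i] - 1e6), p)$Fp
            Sigma <- eps[i] * (1 - eps[i]) *
                (Fp + diag(1 / (2 * nk), 8))
            want <- want + oracleMvnLogLik(x[, i] - eps[i], Sigma, P)
        }
        expect_equal(got, want, tolerance = 1e-8)
    }
    # the neutral ratio against itself is exactly zero and finite
    pn <- sweepParams("neutral")
    expect_equal(compositeLoglik(sim$freqs, pos, NA, pn, Fm, nk) -
                 compositeLoglik(sim$freqs, pos, NA, pn, Fm, nk), 0)
    # allele-label flip leaves the density unchanged (centred symmetry)
    flip <- sim$freqs; flip[, 2] <- 1 - flip[, 2]
    pi1 <- sweepParams("independent", s = 1, x0 = 1e6,
                       selectedPops = selPops)
    expect_equal(compositeLoglik(flip, pos, 1e6, pi1, Fm, nk),
                 compositeLoglik(sim$freqs, pos, 1e6, pi1, Fm, nk),
                 tolerance = 1e-10)
})

test_that("standing(t = 0) and migration(delta = 0) likelihoods agree to 1e-6", {
    sim <- simulateSweepRegion("migration", seed = 3, m = 1,
                               draw = "gaussian", nPerPop = 20)
    Ne <- 7.5e5
    pst <- sweepParams("standing", s = 1, g = 1 / (2 * Ne), t = 0,
                       selectedPops = sim$selectedPops)
    pmi <- sweepParams("migration", s = 1, m = 1, source = "WG",
                       selectedPops = sim$selectedPops)
    llS <- compositeLoglik(sim$freqs, sim$positions, sim$x0, pst,
                           sim$Fhat, sim$nk)
    llM <- compositeLoglik(sim$freqs, sim$positions, sim$x0, pmi,
                           sim$Fhat, sim$nk)
    expect_lt(abs(llS - llM), 1e-6)
})

test_that("the grid search recovers the generating model on single regions", {
    for (mode in c("independent", "migration", "standing")) {
        sim <- simulateSweepRegion(mode, seed = 1, m = 1e-4,
                                   draw = "gaussian", nPerPop = 50)
        fits <- convergenceGridSearch(sim$freqs, sim$positions, sim$Fhat,
            sim$nk, sim$selectedPops, grids = reducedGrids(), stride = 5)
        expect_equal(fits[[1]]@model, mode)
        expect_gt(fits[[1]]@maxRatio, 0)
        if (mode != "standing") {
            # narrow-footprint modes localise the selected site; the
            # broad standing footprint (width log(1/g)/s) does not
            expect_lt(abs(fits[[1]]@mle$x0 - sim$x0), 2e5)
            expect_gt(fits[[1]]@maxRatio, 10)
        }
    }
    # neutral data: all model ratios stay small
    simn <- simulateSweepRegion("independent", seed = 23, s = 1)
    neutral <- simulateNeutralFreqs(defaultCoancestry(), 200, seed = 29)
    gd <- freqsToGenotypes(neutral$freqs, simn$positions, "regionA",
                           nPerPop = 50, seed = 31)
    fr <- popAlleleFreqs(gd)
    fits0 <- convergenceGridSearch(fr, simn$positions, simn$Fhat,
        simn$nk, simn$selectedPops, grids = reducedGrids(), stride = 10)
    sweepFit <- convergenceGridSearch(simn$freqs, simn$positions,
        simn$Fhat, simn$nk, simn$selectedPops, grids = reducedGrids(),
        stride = 10)
    expect_lt(max(vapply(fits0, function(f) f@maxRatio, 0)),
              0.2 * sweepFit[[1]]@maxRatio)
})

test_that("the selection coefficient is recovered within one grid cell", {
    # s is identifiable for the independent and migration models; for the
    # standing model (g, s) trade off along a sweep-width ridge, so s is
    # not separately estimable there (see the vignette)
    res <- modeRecoveryStudy(models = c("independent", "migration"),
                             nRep = 10, seed = 11, s = 0.65)
    expect_gte(mean(res$bestModel == res$mode), 0.8)
    expect_gte(mean(res$sHat %in% c(0.5, 0.65, 0.8)), 0.7)
})

test_that("dense-t refinement separates recent gene flow from old standing variants", {
    # migration-simulated region (full sharing): refined t-hat is 0
    simM <- simulateSweepRegion("migration", seed = 3, m = 1,
                                draw = "gaussian")
    fitsM <- convergenceGridSearch(simM$freqs, simM$positions, simM$Fhat,
        simM$nk, simM$selectedPops, grids = reducedGrids(), stride = 10)
    refM <- refineStandingTime(fitsM[["standing"]], simM$freqs,
        simM$positions, simM$Fhat, simM$nk, simM$selectedPops,
        tGrid = c(0:10, 100, 1000, 3000, 10000))
    expect_equal(refM$tHat, 0)

    # old standing variant on a dense region: refined t-hat >= 1000
    simS <- simulateSweepRegion("standing", seed = 3, g = 1e-6, t = 5000,
        span = 1e6, nSnps = 300, draw = "gaussian")
    fitsS <- convergenceGridSearch(simS$freqs, simS$positions, simS$Fhat,
        simS$nk, simS$selectedPops, grids = reducedGrids(), stride = 10)
    refS <- refineStandingTime(fitsS[["standing"]], simS$freqs,
        simS$positions, simS$Fhat, simS$nk, simS$selectedPops,
        tGrid = c(0:10, 100, 1000, 3000, 10000))
    expect_gte(refS$tHat, 1000)

    # a one-value grid returns that value
    ref1 <- refineStandingTime(fitsS[["standing"]], simS$freqs,
        simS$positions, simS$Fhat, simS$nk, simS$selectedPops,
        tGrid = 42)
    expect_equal(ref1$tHat, 42)
    expect_error(refineStandingTime(fitsS[["standing"]], simS$freqs,
        simS$positions, simS$Fhat, simS$nk, simS$selectedPops,
        tGrid = numeric()), "non-empty")
})
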
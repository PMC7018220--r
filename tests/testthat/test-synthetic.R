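test_that("neutral frequency simulation matches its moments and is seeded", {
    pops <- names(scenarioPopulations())
    zero <- matrix(0, 8, 8, dimnames = list(pops, pops))
    sim <- simulateNeutralFreqs(zero, 50, seed = 1)
    # zero covariance: every population sits exactly at eps
    expect_equal(unname(sim$freqs[3, ]), unname(sim$freqs[1, ]))
    expect_equal(unname(sim$freqs[1, ]), pmin(pmax(sim$eps, 0.01), 0.99))

    # F = c I: empirical variance of (x - eps)/sqrt(eps(1-eps)) recovers c
    cc <- 0.04
    Fc <- diag(cc, 8); dimnames(Fc) <- list(pops, pops)
    simc <- simulateNeutralFreqs(Fc, 50000,
        epsSampler = epsUniform(0.2, 0.8), seed = 2)
    z <- sweep(simc$freqs, 2, simc$eps) /
        rep(sqrt(simc$eps * (1 - simc$eps)), each = 8)
    expect_lt(abs(mean(apply(z, 1, var)) - cc), 0.003)

    # determinism
    expect_identical(simulateNeutralFreqs(Fc, 100, seed = 7),
                     simulateNeutralFreqs(Fc, 100, seed = 7))
})

test_that("coancestry estimation recovers a centred generating matrix", {
    Fc <- centerCoancestry(defaultCoancestry())
    sim <- simulateNeutralFreqs(Fc, 50000,
        epsSampler = epsUniform(0.2, 0.8), seed = 4)
    Fhat <- coancestry(estimateF(sim$freqs))
    expect_lt(max(abs(Fhat - Fc)), 0.02)

    # degenerate input: identical populations per site -> zero matrix
    flat <- matrix(rep(runif(60, 0.2, 0.8), each = 4), 4)
    rownames(flat) <- paste0("p", 1:4)
    expect_lt(max(abs(coancestry(estimateF(flat)))), 1e-5)
})

test_that("sweep injection fixes selected populations near the site and is local", {
    Fm <- defaultCoancestry()
    sel <- c("WG", "BI", "DW", "SPC")
    pos <- seq(1, 4e7, length.out = 1000)
    params <- sweepParams("independent", s = 1, x0 = 1, selectedPops = sel)
    sim <- simulateNeutralFreqs(Fm, 1000, seed = 5)
    swept <- injectSweep(sim$freqs, sim$eps, pos, params, Fm, seed = 6)

    nearIdx <- which(pos < 2e4)     # y ~ 1
    farIdx <- which(pos > 1.5e7)    # y < 1e-6: untouched
    expect_identical(swept[, farIdx], sim$freqs[, farIdx])
    distToFix <- abs(swept[sel, nearIdx] - round(swept[sel, nearIdx]))
    neutDist <- abs(sim$freqs[sel, farIdx] - round(sim$freqs[sel, farIdx]))
    expect_lt(mean(distToFix), 0.25 * mean(neutDist))
    # non-selected populations untouched everywhere
    sPops <- setdiff(rownames(swept), sel)
    expect_identical(swept[sPops, ], sim$freqs[sPops, ])

    # migration at d = 0: cross-population correlation among selected
    # exceeds the neutral F entry (sample-correlation oracle)
    pm <- sweepParams("migration", s = 1, m = 1, source = "WG",
                      x0 = 0, selectedPops = sel)
    posNear <- rep(1, 2000)
    simn <- simulateNeutralFreqs(Fm, 2000, seed = 7)
    sweptM <- suppressWarnings(injectSweep(simn$freqs, simn$eps, posNear,
        pm, Fm, seed = 8, draw = "gaussian"))
    zc <- sweep(sweptM, 2, simn$eps) /
        rep(sqrt(simn$eps * (1 - simn$eps)), each = 8)
    corWB <- cor(zc["WG", ], zc["BI", ])
    expect_gt(corWB, 0.9)
    expect_gt(corWB, coancestry(Fm)["WG", "BI"])

    # x0 outside the span warns but still computes
    expect_warning(injectSweep(sim$freqs, sim$eps, pos + 1e9, params, Fm),
                   "outside")
})

test_that("genotype sampling is binomial in the frequencies and seeded", {
    f <- matrix(rep(c(0, 0.5), 50), nrow = 2,
                dimnames = list(c("a", "b"), NULL))
    gd <- freqsToGenotypes(f, sort(sample.int(1e5, 50)), "chr1",
                           nPerPop = 200, seed = 9)
    g <- dosage(gd)
    pops <- samplePops(gd)
    expect_true(all(g[, pops == "a"] == 0L))
    expect_lt(abs(mean(g[, pops == "b"]) - 1), 0.05)
    expect_error(freqsToGenotypes(f, 1:50, "chr1", nPerPop = 0), "nPerPop")
    expect_identical(dosage(freqsToGenotypes(f, 1:50 * 10L, "c", 3, seed = 4)),
                     dosage(freqsToGenotypes(f, 1:50 * 10L, "c", 3, seed = 4)))
})

test_that("toy annotation places tandem clusters inside their intervals", {
    sl <- c(chr1 = 1e7, chr2 = 1e7)
    clusters <- data.frame(chrom = "chr2", start = 5e6, end = 5e6 + 42300,
                           family = "glycosyltransferase", n = 7)
    genes <- makeToyAnnotation(sl, clusters, nBackground = 30, seed = 3)
    gt <- genes[S4Vectors::mcols(genes)$family == "glycosyltransferase" &
                GenomicRanges::start(genes) >= 5e6 &
                GenomicRanges::end(genes) <= 5e6 + 42300]
    expect_length(gt, 7L)
    expect_length(GenomicRanges::reduce(gt), 7L)  # non-overlapping

    # gff round trip preserves families
    path <- tempfile(fileext = ".gff3")
    makeToyAnnotation(sl, clusters, nBackground = 30, seed = 3, path = path)
    back <- readGeneAnnotation(path)
    expect_equal(sum(S4Vectors::mcols(back)$family ==
                     "glycosyltransferase" &
                     GenomicRanges::start(back) >= 5e6 &
                     GenomicRanges::end(back) <= 5e6 + 42300), 7L)

    # empty spec: background only; determinism
    bg <- makeToyAnnotation(sl, NULL, nBackground = 20, seed = 5)
    expect_length(bg, 40L)
    expect_identical(makeToyAnnotation(sl, clusters, seed = 8),
                     makeToyAnnotation(sl, clusters, seed = 8))
    # over-full cluster errors
    too <- data.frame(chrom = "chr1", start = 1, end = 5000,
                      family = "other", n = 10)
    expect_error(makeToyAnnotation(sl, too, seed = 1), "does not fit")
})

test_that("the default scenario has the study's shape and is seed-determined", {
    sc <- scenarioCache(1)
    cl <- resistanceClass(sc$panel)
    expect_equal(sum(cl == "R"), 4L)
    expect_equal(sum(cl == "S"), 4L)
    expect_equal(ncol(sc$genotypes), 80L)
    expect_length(unique(siteChrom(sc$genotypes)), 5L)
    # variable sites only
    p <- rowMeans(dosage(sc$genotypes), na.rm = TRUE) / 2
    expect_true(all(p > 0 & p < 1))

    sc2 <- makeDefaultScenario(seed = 2)
    expect_equal(ncol(sc2$genotypes), ncol(sc$genotypes))
    expect_false(identical(dosage(sc2$genotypes)[1:50, ],
                           dosage(sc$genotypes)[1:50, ]))
})

test_that("sweep statistics are locally confined", {
    # windows > 5 Mb from the selected site are indistinguishable from a
    # neutral chromosome (two-sample KS on window pi)
    sc <- scenarioCache(1)
    ws <- windowStats(sc$genotypes, sc$panel)
    farSweep <- ws$chrom == "chr2" & (ws$end < 2e8 - 5e6 | ws$start > 2e8 + 5e6)
    neutral <- ws$chrom == "chr5"
    ks <- suppressWarnings(ks.test(ws$piR[farSweep], ws$piR[neutral]))
    expect_gt(ks$p.value, 0.01)
})
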
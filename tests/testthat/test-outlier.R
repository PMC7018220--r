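test_that("population allele frequencies are missing-aware and match counting", {
    set.seed(12)
    G <- matrix(sample(c(0L, 1L, 2L, NA), 100 * 20, TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)), 100)
    colnames(G) <- paste0(rep(c("a", "b"), each = 10), "_", rep(1:10, 2))
    gd <- tinyGenotypes(G)
    fr <- popAlleleFreqs(gd)
    for (i in sample(100, 20)) {
        ga <- G[i, 1:10]
        want <- if (all(is.na(ga))) NA_real_ else
            sum(ga, na.rm = TRUE) / (2 * sum(!is.na(ga)))
        expect_equal(unname(fr["a", i]), want)
    }
    # an all-missing population propagates NA
    G2 <- G; G2[5, 1:10] <- NA
    fr2 <- popAlleleFreqs(tinyGenotypes(G2))
    expect_true(is.na(fr2["a", 5]))
    # dosages 0,1,2 in one population -> frequency 0.5
    G3 <- matrix(c(0L, 1L, 2L), 1)
    colnames(G3) <- paste0("a_", 1:3)
    expect_equal(unname(popAlleleFreqs(tinyGenotypes(G3))[1, 1]), 0.5)
})

test_that("SNP thinning keeps one SNP per kb bin, reproducibly", {
    pos <- as.integer(c(100, 900, 1500, 2100, 2900, 5000))
    G <- matrix(rbinom(6 * 8, 2, 0.5), 6)
    colnames(G) <- paste0("a_", 1:8)
    gd <- tinyGenotypes(G, pos = pos)
    thin <- thinSnps(gd, bpWindow = 1000, seed = 4)
    expect_equal(nrow(thin), 4L)  # bins (0,1]k, (1,2]k... -> 4 occupied
    bins <- (sitePos(thin) - 1L) %/% 1000L
    expect_false(anyDuplicated(bins) > 0)
    # one SNP per bin already: identity
    sparse <- tinyGenotypes(G, pos = as.integer(seq(100, 5100, 1000)))
    expect_identical(dosage(thinSnps(sparse, seed = 1)), dosage(sparse))
    expect_identical(sitePos(thinSnps(gd, seed = 9)),
                     sitePos(thinSnps(gd, seed = 9)))
})

test_that("the resistance scan flags by the joint empirical rule", {
    sc <- scenarioCache(1)
    thin <- thinSnps(sc$genotypes, seed = 51)
    scan <- resistanceScan(thin, sc$panel)
    usable <- !is.na(scan$score)
    # joint criterion caps the flag rate at the score fraction
    expect_lte(mean(scan$outlier[usable]), 0.01)
    # flipping the environment sign flips rho but not the flags
    flipped <- resistanceScan(thin, sc$panel,
        classes = setNames(ifelse(resistanceClass(sc$panel) == "R", "S",
                                  "R"), populations(sc$panel)))
    expect_equal(flipped$rho, -scan$rho, tolerance = 1e-12)
    expect_equal(flipped$outlier, scan$outlier)
    # flagged SNPs concentrate near the injected sweeps
    hit <- scan$outlier
    nearSweep <- siteChrom(thin) %in% c("chr1", "chr2", "chr3") &
        abs(sitePos(thin) - 2e8) < 1e6
    expect_gt(mean(nearSweep[hit]), 0.8)
})

test_that("scan flags are invariant to sample order and allele flips", {
    sc <- scenarioCache(1)
    thin <- thinSnps(sc$genotypes, seed = 51)
    scan <- resistanceScan(thin, sc$panel)
    perm <- sample(ncol(thin))
    thinP <- thin[, perm]
    scanP <- resistanceScan(thinP, sc$panel)
    expect_equal(scanP$outlier, scan$outlier)
    # allele flip: dosage 2 - g
    gF <- 2L - dosage(thin)
    thinF <- GenotypeData(gF, chrom = siteChrom(thin),
        pos = sitePos(thin), ref = rep("T", nrow(thin)),
        alt = rep("A", nrow(thin)), ancestral = rep("T", nrow(thin)),
        samples = colnames(thin),
        populations = unname(samplePops(thin)))
    scanF <- resistanceScan(thinF, sc$panel)
    expect_equal(scanF$outlier, scan$outlier)
    expect_equal(scanF$score, scan$score, tolerance = 1e-12)
})

test_that("a SNP with identical frequencies everywhere is excluded", {
    G <- rbind(rep(1L, 40),
               rbinom(40, 2, 0.5))
    colnames(G) <- paste0(rep(c("r1", "r2", "s1", "s2"), each = 10), "_",
                          rep(1:10, 4))
    panel <- tinyPanel(c("r1", "r2", "s1", "s2"), c("r1", "r2"))
    scan <- resistanceScan(tinyGenotypes(G), panel)
    expect_true(is.na(scan$rho[1]))
    expect_false(scan$outlier[1])
})

test_that("under a global null the flag rate stays at or below the score fraction", {
    set.seed(14)
    G <- matrix(rbinom(4000 * 80, 2, rep(runif(4000, 0.1, 0.9), 80)),
                4000)
    colnames(G) <- paste0(rep(names(scenarioPopulations()), each = 10),
                          "_", rep(1:10, 8))
    gd <- tinyGenotypes(G, pos = sort(sample.int(4e7, 4000)))
    scan <- resistanceScan(gd, eightPanel())
    usable <- !is.na(scan$score)
    expect_lte(sum(scan$outlier), floor(sum(usable) * 0.01))
})

test_that("randomized groupings are admissible, seeded, and non-exceptional on null data", {
    sc <- scenarioCache(1)
    pops <- populations(sc$panel)
    trueR <- names(which(resistanceClass(sc$panel) == "R"))
    splits <- sweepmode:::.admissibleSplits(pops, trueR)
    expect_length(splits, 34L)  # choose(8,4)/2 - 1
    keys <- vapply(splits, function(s) paste(sort(s), collapse = "|"), "")
    expect_false(paste(sort(trueR), collapse = "|") %in% keys)

    thin <- thinSnps(sc$genotypes, seed = 51)
    r1 <- randomizedGroupingNull(thin, sc$panel, nRand = 8, seed = 2)
    r2 <- randomizedGroupingNull(thin, sc$panel, nRand = 8, seed = 2)
    expect_identical(r1$null, r2$null)
    # the true grouping is exceptional on sweep-bearing data
    expect_lte(r1$fractionRegions, 0.15)
    expect_message(randomizedGroupingNull(thin, sc$panel, nRand = 40,
                                          seed = 2), "replacement")

    # pure-null data: the observed grouping is not exceptional
    set.seed(15)
    G <- matrix(rbinom(2000 * 80, 2, rep(runif(2000, 0.1, 0.9), 80)),
                2000)
    colnames(G) <- paste0(rep(pops, each = 10), "_", rep(1:10, 8))
    gd0 <- tinyGenotypes(G, pos = sort(sample.int(4e7, 2000)))
    r0 <- randomizedGroupingNull(gd0, eightPanel(), nRand = 20, seed = 3)
    expect_gte(r0$fractionOutliers, 0.05)
})
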
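test_that("per-site diversity matches the unbiased heterozygosity formula", {
    expect_equal(sitePi(0, 10), 0)
    expect_equal(sitePi(10, 10), 0)
    expect_equal(sitePi(2, 4), 2 / 3)
    expect_true(is.na(sitePi(1, 1)))
    # window theta_pi equals the all-pairs difference average on haplotypes
    set.seed(21)
    for (rep in 1:5) {
        n <- sample(4:10, 1); m <- sample(10:40, 1)
        hap <- matrix(rbinom(n * m, 1, runif(1, 0.2, 0.8)), n)
        calt <- colSums(hap)
        expect_equal(sum(sitePi(calt, n)), oraclePairwisePi(hap),
                     tolerance = 1e-12)
    }
})

test_that("windowed D and H agree with direct formula evaluation", {
    # single site, n = 4 alleles, derived count 3:
    # theta_pi = 0.5, theta_H = 1.5, H = -1
    expect_equal(oracleFayWuH(3, 4), -1)
    # assemble a random 25-SNP window and compare against the oracles
    set.seed(31)
    nInd <- 12
    G <- matrix(rbinom(25 * nInd, 2, runif(25, 0.1, 0.9)), 25,
                dimnames = list(NULL, paste0(rep(c("rA", "sA"),
                    each = nInd / 2), "_", rep(1:(nInd / 2), 2))))
    gdw <- tinyGenotypes(G)
    panel <- tinyPanel(c("rA", "sA"), "rA")
    ws <- windowStats(gdw, panel, windowSize = 25)
    expect_equal(nrow(ws), 1L)
    rSamp <- grepl("^rA", colnames(G))
    caltR <- rowSums(G[, rSamp])
    nR <- 2 * sum(rSamp)
    expect_equal(ws$piR, sum(sitePi(caltR, nR)))
    expect_equal(ws$tajimaDR, oracleTajimaD(caltR, nR), tolerance = 1e-12)
    # ancestral = ref, so derived counts are the alt counts
    expect_equal(ws$fayWuHR, oracleFayWuH(caltR[caltR > 0 & caltR < nR],
                                          nR), tolerance = 1e-12)

    # all-singleton window: D < 0 (excess rare variants)
    Gs <- matrix(0L, 25, nInd, dimnames = dimnames(G))
    Gs[cbind(1:25, sample(which(rSamp), 25, replace = TRUE))] <- 1L
    Gs[cbind(1:25, sample(which(!rSamp), 25, replace = TRUE))] <- 1L
    wsS <- windowStats(tinyGenotypes(Gs), panel, windowSize = 25)
    expect_lt(wsS$tajimaDR, 0)

    # no segregating sites in the group -> D and H are NA, not 0
    Gm <- matrix(0L, 25, nInd, dimnames = dimnames(G))
    Gm[, !rSamp] <- 1L  # S group polymorphic-free too? keep R monomorphic
    wsM <- windowStats(tinyGenotypes(Gm), panel, windowSize = 25)
    expect_true(is.na(wsM$tajimaDR))
    expect_true(is.na(wsM$fayWuHR))

    # trailing partial windows are dropped
    G2 <- rbind(G, G[1:10, ])
    ws2 <- windowStats(tinyGenotypes(G2), panel, windowSize = 25)
    expect_equal(nrow(ws2), 1L)
})

test_that("Nei's G_ST matches hand evaluation and its boundary cases", {
    expect_equal(neiGst(c(0.3, 0.3, 0.3)), 0)
    expect_equal(neiGst(c(0, 1)), 1)
    expect_equal(neiGst(c(0.2, 0.8)), 0.36)
    expect_error(neiGst(0.5), "2 populations")
    set.seed(41)
    for (rep in 1:20) {
        p <- runif(sample(2:6, 1))
        expect_equal(neiGst(p), oracleGst(p), tolerance = 1e-12)
    }
})

test_that("Weir-Cockerham theta matches an independently coded oracle", {
    # identical populations at p = 0.5: estimate clamps to 0
    g <- matrix(1L, 4, 20)
    colnames(g) <- paste0(rep(c("a", "b"), each = 10), "_", rep(1:10, 2))
    gd <- tinyGenotypes(g)
    expect_equal(unname(wcFst(gd, "a", "b")), rep(0, 4))

    # fixed opposite alleles: theta = 1
    g2 <- cbind(matrix(0L, 3, 10), matrix(2L, 3, 10))
    colnames(g2) <- colnames(g)
    expect_equal(unname(wcFst(tinyGenotypes(g2), "a", "b")), rep(1, 3))

    # random instances against the a/b/c-component oracle
    set.seed(51)
    for (rep in 1:30) {
        n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
        g1 <- rbinom(n1, 2, 0.9); g2v <- rbinom(n2, 2, 0.3)
        G <- matrix(c(g1, g2v), 1)
        colnames(G) <- paste0(rep(c("a", "b"), c(n1, n2)), "_",
                              c(seq_len(n1), seq_len(n2)))
        got <- wcFst(tinyGenotypes(G), "a", "b")
        want <- oracleWC84(n1, mean(g1) / 2, mean(g1 == 1),
                           n2, mean(g2v) / 2, mean(g2v == 1))
        expect_equal(unname(got), want, tolerance = 1e-10)
    }
})

test_that("group mean F_ST behaves at the null and under the bootstrap", {
    # zero-differentiation simulation: clamped estimator mean is small
    set.seed(61)
    G <- matrix(rbinom(200 * 40, 2, rep(runif(200, 0.3, 0.7), 40)), 200)
    colnames(G) <- paste0(rep(c("r1", "r2", "s1", "s2"), each = 10), "_",
                          rep(1:10, 4))
    gd <- tinyGenotypes(G)
    panel <- tinyPanel(c("r1", "r2", "s1", "s2"), c("r1", "r2"))
    res <- groupMeanFst(gd, panel, "R", nBoot = 200, seed = 3)
    expect_lt(res$mean, 0.05)
    expect_lt(res$ci[1], res$mean)
    # nBoot = 1: the interval collapses onto the single replicate
    one <- groupMeanFst(gd, panel, "R", nBoot = 1, seed = 3)
    expect_equal(one$ci[1], one$ci[2])
    expect_error(groupMeanFst(gd, tinyPanel(c("r1", "r2", "s1", "s2"),
                                            "r1"), "R"), "2 populations")
})

test_that("among-class F_ST is higher at divergently swept loci than genome-wide", {
    # independent-mode sweep: resistant populations fix different
    # haplotypes, so their pairwise differentiation at sweep loci exceeds
    # the genome-wide background
    sc <- scenarioCache(1)
    chrom <- siteChrom(sc$genotypes); pos <- sitePos(sc$genotypes)
    sweepSites <- which(chrom == "chr1" & abs(pos - 2e8) < 5e4)
    neutralSites <- which(chrom %in% c("chr4", "chr5"))
    fstSweep <- groupMeanFst(sc$genotypes, sc$panel, "R", nBoot = 50,
                             seed = 5, sites = sweepSites)
    fstNeutral <- groupMeanFst(sc$genotypes, sc$panel, "R", nBoot = 50,
                               seed = 5, sites = neutralSites)
    expect_gt(fstSweep$mean, fstNeutral$mean)
})

test_that("population summaries give Ho, He and F_IS correctly", {
    # all heterozygotes: Ho = 1, F_IS < 0
    g <- matrix(1L, 20, 10)
    colnames(g) <- paste0("a_", 1:10)
    s1 <- popSummaryStats(tinyGenotypes(g))
    expect_equal(s1$Ho, 1)
    expect_lt(s1$Fis, 0)
    # fully selfed (homozygous) population: Ho = 0, F_IS = 1
    g2 <- matrix(sample(c(0L, 2L), 200, TRUE), 20, 10)
    colnames(g2) <- colnames(g)
    s2 <- popSummaryStats(tinyGenotypes(g2))
    expect_equal(s2$Ho, 0)
    expect_equal(s2$Fis, 1)
    # Hardy-Weinberg simulation: F_IS ~ 0
    set.seed(71)
    g3 <- matrix(rbinom(3000 * 30, 2, rep(runif(3000, 0.2, 0.8), 30)),
                 3000)
    colnames(g3) <- paste0("a_", 1:30)
    s3 <- popSummaryStats(tinyGenotypes(g3))
    expect_lt(abs(s3$Fis), 0.02)
})

test_that("candidate-gene association tests behave at their boundaries", {
    set.seed(81)
    # SNP 1: identical in both classes; SNP 2: perfectly separating
    G <- rbind(rep(1L, 40),
               c(rep(2L, 20), rep(0L, 20)),
               rbinom(40, 2, 0.5))
    colnames(G) <- paste0(rep(c("r1", "r2", "s1", "s2"), each = 10), "_",
                          rep(1:10, 4))
    gd <- tinyGenotypes(G)
    # survival aligned exactly with the class split so a perfectly
    # separating SNP attains |r| = 1
    panel <- suppressWarnings(PopulationPanel(c("r1", "r2", "s1", "s2"),
        c(0.9, 0.9, 0.1, 0.1), "P"))
    res <- candidateGeneAssoc(gd, panel)
    expect_equal(res$chi2[1], 0, tolerance = 1e-9)
    expect_equal(res$chisqP[1], 1, tolerance = 1e-9)
    expect_equal(abs(res$pearsonR[2]), 1, tolerance = 1e-6)
    # BH adjustment matches the step-up definition
    set.seed(82)
    G0 <- matrix(rbinom(10 * 40, 2, rep(runif(10, 0.3, 0.7), 40)), 10)
    colnames(G0) <- colnames(G)
    r0 <- candidateGeneAssoc(tinyGenotypes(G0), panel)
    ok <- !is.na(r0$chisqP)
    expect_equal(r0$chisqPAdj[ok], oracleBH(r0$chisqP[ok]))
    # BH output is monotone nondecreasing in p-value rank
    o <- order(r0$chisqP[ok])
    expect_true(all(diff(r0$chisqPAdj[ok][o]) >= -1e-12))
})

test_that("statistics are invariant to allele-label flips", {
    set.seed(91)
    G <- matrix(rbinom(50 * 40, 2, rep(runif(50, 0.2, 0.8), 40)), 50)
    colnames(G) <- paste0(rep(c("r1", "r2", "s1", "s2"), each = 10), "_",
                          rep(1:10, 4))
    panel <- tinyPanel(c("r1", "r2", "s1", "s2"), c("r1", "r2"))
    gd <- tinyGenotypes(G, ancestral = "A")
    # flip dosages AND the ancestral label (now the alt allele)
    gdF <- tinyGenotypes(2L - G, ancestral = "T")
    w1 <- windowStats(gd, panel, windowSize = 25)
    w2 <- windowStats(gdF, panel, windowSize = 25)
    expect_equal(w1$piR, w2$piR)
    expect_equal(w1$tajimaDR, w2$tajimaDR)
    expect_equal(w1$meanGst, w2$meanGst)
    # flipping ancestral with the alleles leaves H unchanged
    expect_equal(w1$fayWuHR, w2$fayWuHR)
    expect_equal(unname(wcFst(gd, "r1", "s1")),
                 unname(wcFst(gdF, "r1", "s1")))
})

test_that("composite r2 summarises linkage and finds elevated spans", {
    set.seed(101)
    base <- rbinom(80, 2, 0.5)
    # duplicated SNP column gives r2 = 1; independent SNPs give ~1/(n-1)
    G <- rbind(base, base,
               matrix(rbinom(60 * 80, 2, rep(runif(60, 0.2, 0.8), 80)),
                      60))
    colnames(G) <- paste0("a_", 1:80)
    gd <- tinyGenotypes(G, pos = seq_len(nrow(G)) * 1000L)
    ld <- ldR2(gd, "chr1", windowSize = 10)
    R2dup <- suppressWarnings(cor(G[1, ], G[2, ]))^2
    expect_equal(R2dup, 1)
    # chromosome mean dominated by independent pairs: near 1/(n-1)
    expect_lt(ld$meanR2, 3 / 79)
    expect_gt(ld$meanR2, 0.2 / 79)

    # permutation oracle: breaking columns kills r2 down to the same
    # sampling floor
    Gp <- t(apply(G, 1, sample))
    colnames(Gp) <- colnames(G)
    ldp <- ldR2(tinyGenotypes(Gp, pos = seq_len(nrow(G)) * 1000L), "chr1",
                windowSize = 10)
    expect_lt(abs(ld$meanR2 - ldp$meanR2), 0.02)

    # a block of perfectly linked SNPs yields one span covering it
    block <- matrix(rep(base, 12), 12, byrow = TRUE)
    Gb <- rbind(matrix(rbinom(20 * 80, 2, rep(runif(20, .3, .7), 80)), 20),
                block,
                matrix(rbinom(20 * 80, 2, rep(runif(20, .3, .7), 80)), 20))
    colnames(Gb) <- colnames(G)
    ldb <- ldR2(tinyGenotypes(Gb, pos = seq_len(nrow(Gb)) * 1000L),
                "chr1", windowSize = 10)
    expect_equal(nrow(ldb$spans), 1L)
    # the detected span sits on the linked block
    expect_gte(ldb$spans$start, 21000)
    expect_lte(ldb$spans$end, 32000)
})
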
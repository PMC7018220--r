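#' Per-population alternate-allele frequencies
#'
#' Missing-aware frequency matrix: populations x sites, NA where a
#' population has no genotyped sample at a site.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param panel optional panel fixing the population order
#' @return numeric matrix, populations x sites
#' @export
popAlleleFreqs <- function(x, panel = NULL) {
    sp <- samplePops(x)
    pops <- if (is.null(panel)) unique(unname(sp))
            else intersect(populations(panel), unique(unname(sp)))
    g <- dosage(x)
    out <- t(vapply(pops, function(pk) {
        gs <- g[, sp == pk, drop = FALSE]
        n <- 2 * rowSums(!is.na(gs))
        ifelse(n > 0, rowSums(gs, na.rm = TRUE) / n, NA_real_)
    }, numeric(nrow(g))))
    colnames(out) <- rownames(g)
    out
}

#' Randomly thin SNPs to one per base-pair window
#'
#' Retains exactly one uniformly chosen SNP per non-empty \code{bpWindow}
#' bin per chromosome (reducing the effect of linkage among test SNPs
#' before outlier testing). Seeded, hence reproducible.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param bpWindow bin width in bp (default 1000)
#' @param seed integer seed
#' @return thinned \linkS4class{GenotypeData}
#' @export
thinSnps <- function(x, bpWindow = 1000, seed = 1) {
    chrom <- siteChrom(x); pos <- sitePos(x)
    bin <- paste(chrom, (pos - 1L) %/% bpWindow)
    set.seed(seed)
    keep <- unlist(lapply(split(seq_along(bin), bin), function(i)
        if (length(i) == 1L) i else i[sample.int(length(i), 1L)]),
        use.names = FALSE)
    x[sort(keep), ]
}

#' Scan SNPs for association with the resistance phenotype
#'
#' Two empirical criteria per SNP, mirroring a joint differentiation +
#' environmental-correlation outlier rule: a differentiation score (the
#' pooled R-versus-S Nei G_ST, a documented stand-in for a Bayes factor
#' from an MCMC differentiation model) and the Spearman correlation rho
#' between per-population allele frequency and the environment (class
#' coded -1/+1, or the survival proportion). A SNP is flagged iff its
#' score lies in the top \code{topScore} fraction AND |rho| lies in the
#' top \code{topRho} fraction of the empirical distributions, so the flag
#' rate is at most \code{topScore} by construction. SNPs with identical
#' frequencies in every population (rho undefined) are excluded.
#'
#' @param x a \linkS4class{GenotypeData} (typically thinned; see
#'   \code{\link{thinSnps}})
#' @param panel a \linkS4class{PopulationPanel}
#' @param envCoding \code{"binary"} (-1 susceptible / +1 resistant) or
#'   \code{"survival"}
#' @param topScore top fraction for the differentiation score (default
#'   0.01)
#' @param topRho top fraction for |rho| (default 0.05)
#' @param classes optional named class override (used by the
#'   randomized-grouping null)
#' @return data.frame: chrom, pos, score, rho, scoreQ, rhoQ, outlier;
#'   excluded SNPs carry NA statistics and FALSE flags
#' @export
resistanceScan <- function(x, panel, envCoding = c("binary", "survival"),
                           topScore = 0.01, topRho = 0.05,
                           classes = NULL) {
    envCoding <- match.arg(envCoding)
    if (is.null(classes)) classes <- resistanceClass(panel)
    freqs <- popAlleleFreqs(x, panel)
    pops <- rownames(freqs)
    if (length(pops) < 4 || length(unique(classes[pops])) < 2)
        stop("need >= 4 populations with both classes present")
    env <- if (envCoding == "binary")
        ifelse(classes[pops] == "R", 1, -1) else survivalProp(panel)[pops]
    sp <- samplePops(x)
    rSamp <- names(sp)[classes[sp] == "R"]
    sSamp <- names(sp)[classes[sp] == "S"]
    g <- dosage(x)
    pooled <- function(samp) {
        gs <- g[, samp, drop = FALSE]
        n <- 2 * rowSums(!is.na(gs))
        ifelse(n > 0, rowSums(gs, na.rm = TRUE) / n, NA_real_)
    }
    score <- .neiGstPair(pooled(rSamp), pooled(sSamp))
    # Spearman rho per site across populations
    envRank <- rank(env)
    rho <- apply(freqs, 2, function(fv) {
        ok <- !is.na(fv)
        if (sum(ok) < 3 || sd(fv[ok]) == 0) return(NA_real_)
        stats::cor(rank(fv[ok]), envRank[ok])
    })
    usable <- !is.na(score) & !is.na(rho)
    n <- sum(usable)
    kScore <- max(1L, floor(n * topScore))
    kRho <- max(1L, floor(n * topRho))
    scoreRank <- rhoRank <- rep(NA_real_, length(score))
    scoreRank[usable] <- rank(-score[usable], ties.method = "first")
    rhoRank[usable] <- rank(-abs(rho[usable]), ties.method = "first")
    flag <- !is.na(scoreRank) & scoreRank <= kScore & rhoRank <= kRho
    data.frame(chrom = siteChrom(x), pos = sitePos(x),
        score = score, rho = rho,
        scoreQ = ifelse(usable, 1 - (scoreRank - 1) / n, NA),
        rhoQ = ifelse(usable, 1 - (rhoRank - 1) / n, NA),
        outlier = flag, row.names = NULL)
}

# all balanced splits of the populations into two groups of equal size,
# as a list of character vectors (the "R"-labelled half); complements and
# the true grouping are removed
.admissibleSplits <- function(pops, trueR) {
    half <- length(pops) / 2
    cmb <- utils::combn(pops, half, simplify = FALSE)
    keyOf <- function(s) paste(sort(s), collapse = "|")
    seen <- character(); out <- list()
    for (s in cmb) {
        k <- keyOf(s); kc <- keyOf(setdiff(pops, s))
        if (k %in% seen || kc %in% seen) next
        seen <- c(seen, k)
        if (k == keyOf(trueR) || kc == keyOf(trueR)) next
        out[[length(out) + 1L]] <- s
    }
    out
}

#' Randomized-grouping null for the outlier scan
#'
#' Re-runs the scan-and-delimit pipeline after randomly reassigning the
#' populations to two balanced groups (never the true resistance grouping
#' or its complement), recording for each randomization the flagged-SNP
#' count and the number of delimited regions. The summary reports the
#' fraction of randomizations reaching (a) at least the observed region
#' count and (b) at least the observed outlier count. For eight
#' populations there are 34 admissible balanced splits; requesting more
#' randomizations samples with replacement (with a message).
#'
#' @param x a (thinned) \linkS4class{GenotypeData}
#' @param panel a \linkS4class{PopulationPanel}
#' @param nRand number of randomizations (default 100)
#' @param seed integer seed
#' @param maxGap,minOutliers region-delimitation parameters
#' @param ... further arguments to \code{\link{resistanceScan}}
#' @return list with \code{observed} (outliers, regions), \code{null}
#'   (per-randomization data.frame), \code{fractionRegions},
#'   \code{fractionOutliers}
#' @export
randomizedGroupingNull <- function(x, panel, nRand = 100, seed = 1,
                                   maxGap = 2e6, minOutliers = 5, ...) {
    cl <- resistanceClass(panel)
    pops <- intersect(populations(panel), populations(x))
    trueR <- names(cl)[cl == "R"]
    obsScan <- resistanceScan(x, panel, ...)
    obsReg <- delimitRegions(obsScan, maxGap = maxGap,
                             minOutliers = minOutliers)
    obs <- c(outliers = sum(obsScan$outlier),
             regions = length(regions(obsReg)))
    splits <- .admissibleSplits(pops, trueR)
    set.seed(seed)
    if (nRand > length(splits)) {
        message("nRand exceeds the ", length(splits),
                " distinct admissible splits; sampling with replacement")
        pick <- sample.int(length(splits), nRand, replace = TRUE)
    } else pick <- sample.int(length(splits), nRand)
    nullDf <- do.call(rbind, lapply(seq_along(pick), function(i) {
        rg <- splits[[pick[i]]]
        classes <- setNames(ifelse(pops %in% rg, "R", "S"), pops)
        sc <- resistanceScan(x, panel, classes = classes, ...)
        rg2 <- delimitRegions(sc, maxGap = maxGap,
                              minOutliers = minOutliers)
        data.frame(rand = i, outliers = sum(sc$outlier),
                   regions = length(regions(rg2)))
    }))
    list(observed = obs, null = nullDf,
         fractionRegions = mean(nullDf$regions >= obs["regions"]),
         fractionOutliers = mean(nullDf$outliers >= obs["outliers"]))
}
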
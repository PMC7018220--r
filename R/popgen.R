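#' Per-site nucleotide diversity from allele counts
#'
#' Unbiased per-site heterozygosity 2 c (n - c) / (n (n - 1)) for derived
#' (or alternate) allele count c among n sampled alleles; summed over a
#' window this equals the average number of pairwise differences (theta_pi).
#' Sites with fewer than 2 alleles yield NA and are skipped by callers.
#'
#' @param c allele count (vectorised)
#' @param n total non-missing allele count (vectorised)
#' @return numeric vector of per-site diversity
#' @examples
#' sitePi(2, 4)  # 2/3
#' @export
sitePi <- function(c, n) {
    out <- 2 * c * (n - c) / (n * (n - 1))
    out[rep_len(n < 2, length(out))] <- NA_real_
    out
}

# Tajima's D normalising constants for sample size n (alleles)
.tajimaConstants <- function(n) {
    i <- seq_len(n - 1)
    a1 <- sum(1 / i); a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# window-level D/H/pi for one pooled sample group
.groupWindowStats <- function(calt, n, cd, idx) {
    ok <- idx[n[idx] >= 2]
    thetaPi <- sum(sitePi(calt[ok], n[ok]))
    S <- sum(calt[ok] > 0 & calt[ok] < n[ok])
    nbar <- round(mean(n[ok]))
    D <- NA_real_
    if (S > 0 && nbar >= 3) {
        k <- .tajimaConstants(nbar)
        D <- (thetaPi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
    }
    # H over sites with an ancestral call that segregate within the
    # group (sample-fixed sites are substitutions, not polymorphisms, and
    # the theta_H estimator is defined over segregating sites); theta_pi
    # and theta_H are summed over the same sites so the difference is
    # coherent
    hok <- ok[!is.na(cd[ok]) & cd[ok] > 0 & cd[ok] < n[ok]]
    H <- NA_real_
    if (length(hok)) {
        thetaH <- sum(2 * cd[hok]^2 / (n[hok] * (n[hok] - 1)))
        H <- sum(sitePi(cd[hok], n[hok])) - thetaH
    }
    list(pi = thetaPi, D = D, H = H, S = S)
}

#' Windowed diversity and differentiation statistics for pooled groups
#'
#' Splits each chromosome into consecutive, non-overlapping windows of
#' \code{windowSize} SNPs (trailing partial windows are dropped) and
#' computes, for the pooled resistant (R) and pooled susceptible (S)
#' sample groups: nucleotide diversity theta_pi, Tajima's D (standard
#' constants, with n the rounded mean non-missing allele count over the
#' window), unnormalised Fay & Wu's H = theta_pi - theta_H (theta_H =
#' sum 2 c_d^2 / (n (n-1)) over derived counts; sites lacking an ancestral
#' call are skipped for H only), the log10 ratio pi_S/pi_R, and the mean
#' per-site Nei G_ST between the pooled groups. Windows with no
#' segregating sites report D and H as NA, never 0.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param panel a \linkS4class{PopulationPanel} giving each population's
#'   resistance class
#' @param windowSize SNPs per window (default 25)
#' @return data.frame, one row per window
#' @export
windowStats <- function(x, panel, windowSize = 25) {
    cl <- resistanceClass(panel)
    pops <- samplePops(x)
    rSamp <- names(pops)[cl[pops] == "R"]
    sSamp <- names(pops)[cl[pops] == "S"]
    if (!length(rSamp) || !length(sSamp))
        stop("both resistance classes must be present")
    g <- dosage(x)
    grp <- function(samp) {
        gs <- g[, samp, drop = FALSE]
        n <- 2L * rowSums(!is.na(gs))
        calt <- rowSums(gs, na.rm = TRUE)
        dc <- derivedCounts(x, samp)
        list(n = n, calt = calt, cd = dc$cd)
    }
    R <- grp(rSamp); S <- grp(sSamp)
    pR <- ifelse(R$n > 0, R$calt / R$n, NA)
    pS <- ifelse(S$n > 0, S$calt / S$n, NA)
    gstSite <- .neiGstPair(pR, pS)
    chrom <- siteChrom(x); pos <- sitePos(x)
    out <- list()
    for (ch in unique(chrom)) {
        sites <- which(chrom == ch)
        nw <- length(sites) %/% windowSize
        for (w in seq_len(nw)) {
            idx <- sites[((w - 1) * windowSize + 1):(w * windowSize)]
            r <- .groupWindowStats(R$calt, R$n, R$cd, idx)
            s <- .groupWindowStats(S$calt, S$n, S$cd, idx)
            out[[length(out) + 1L]] <- data.frame(chrom = ch,
                start = pos[idx[1]], end = pos[idx[length(idx)]],
                nSnps = length(idx),
                piR = r$pi, piS = s$pi,
                log10PiRatio = ifelse(r$pi > 0, log10(s$pi / r$pi), NA),
                tajimaDR = r$D, tajimaDS = s$D,
                fayWuHR = r$H, fayWuHS = s$H,
                meanGst = mean(gstSite[idx], na.rm = TRUE))
        }
    }
    do.call(rbind, out)
}

# Nei G_ST for exactly two frequency vectors (vectorised over sites)
.neiGstPair <- function(p1, p2) {
    hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    pbar <- (p1 + p2) / 2
    ht <- 2 * pbar * (1 - pbar)
    ifelse(is.na(ht), NA, ifelse(ht == 0, 0, 1 - hs / ht))
}

#' Nei's G_ST across populations at a site
#'
#' G_ST = 1 - H_S / H_T with H_S the unweighted mean within-population
#' expected heterozygosity and H_T the expected heterozygosity at the mean
#' allele frequency. Sites monomorphic overall return 0. Accepts a
#' frequency vector (one site) or a populations x sites matrix.
#'
#' @param freqs numeric vector (one site) or matrix (populations x sites)
#' @return scalar or per-site vector
#' @examples
#' neiGst(c(0.2, 0.8))  # 0.36
#' @export
neiGst <- function(freqs) {
    if (is.matrix(freqs)) {
        if (nrow(freqs) < 2) stop("need at least 2 populations")
        hs <- colMeans(2 * freqs * (1 - freqs))
        pbar <- colMeans(freqs)
        ht <- 2 * pbar * (1 - pbar)
        return(ifelse(ht == 0, 0, 1 - hs / ht))
    }
    if (length(freqs) < 2) stop("need at least 2 populations")
    neiGst(matrix(freqs, ncol = 1))[1]
}

# Weir-Cockerham (1984) two-population theta-hat from per-site summaries:
# n1, n2 diploid counts; p1, p2 alt frequencies; h1, h2 observed het
# fractions. Vectorised over sites. Negative estimates are clamped to 0;
# sites monomorphic in both populations give NA.
.wcThetaCore <- function(n1, p1, h1, n2, p2, h2) {
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r -
                              hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                (2 * nbar - 1) * hbar / (4 * nbar))
    cc <- hbar / 2
    theta <- a / (a + b + cc)
    theta <- ifelse(pbar == 0 | pbar == 1, NA, theta)
    pmax(theta, 0)
}

#' Weir-Cockerham pairwise F_ST per SNP
#'
#' The 1984 moment estimator theta-hat for a pair of populations, computed
#' per SNP from allele frequencies and observed heterozygote counts, with
#' negative estimates set to zero. SNPs monomorphic in both populations
#' are undefined (NA) and excluded from averages.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param pop1,pop2 population identifiers
#' @return numeric vector, one theta-hat per SNP
#' @export
wcFst <- function(x, pop1, pop2) {
    pops <- samplePops(x)
    g1 <- dosage(x)[, pops == pop1, drop = FALSE]
    g2 <- dosage(x)[, pops == pop2, drop = FALSE]
    n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
    p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
    p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
    h1 <- rowMeans(g1 == 1L, na.rm = TRUE)
    h2 <- rowMeans(g2 == 1L, na.rm = TRUE)
    out <- .wcThetaCore(n1, p1, h1, n2, p2, h2)
    out[n1 < 1 | n2 < 1] <- NA
    out
}

#' Mean pairwise F_ST within a resistance class, with bootstrap CI
#'
#' Averages the per-SNP Weir-Cockerham theta-hat over every population
#' pair in the class and over loci, and attaches a 95% confidence interval
#' from \code{nBoot} locus bootstraps (loci resampled with replacement;
#' the 2.5 and 97.5 percentiles of the replicate means).
#'
#' @param x a \linkS4class{GenotypeData}
#' @param panel a \linkS4class{PopulationPanel}
#' @param group \code{"R"} or \code{"S"}
#' @param nBoot bootstrap replicates (default 1000)
#' @param seed integer seed
#' @param sites optional site subset (indices or names)
#' @return list with \code{mean}, \code{ci} (length 2), \code{nLoci}
#' @export
groupMeanFst <- function(x, panel, group = "R", nBoot = 1000, seed = 1,
                         sites = NULL) {
    cl <- resistanceClass(panel)
    pops <- intersect(names(cl)[cl == group], populations(x))
    if (length(pops) < 2) stop("need at least 2 populations in group")
    if (!is.null(sites)) x <- x[sites, ]
    prs <- utils::combn(pops, 2)
    theta <- vapply(seq_len(ncol(prs)), function(i)
        wcFst(x, prs[1, i], prs[2, i]), numeric(nrow(x)))
    theta <- matrix(theta, nrow = nrow(x))
    m <- mean(theta, na.rm = TRUE)
    set.seed(seed)
    reps <- vapply(seq_len(nBoot), function(b) {
        idx <- sample.int(nrow(theta), replace = TRUE)
        mean(theta[idx, ], na.rm = TRUE)
    }, 0)
    list(mean = m, ci = unname(quantile(reps, c(0.025, 0.975),
                                        na.rm = TRUE)),
         nLoci = nrow(theta))
}

#' Per-population summary statistics (Ho, He, F_IS)
#'
#' Observed heterozygosity is the fraction of heterozygous calls; expected
#' heterozygosity is 2p(1-p) with the n/(n-1) small-sample correction
#' (n = non-missing allele count); F_IS = 1 - Ho/He over sites polymorphic
#' within the population. Populations with no polymorphic site get NA
#' F_IS.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param panel optional panel restricting/ordering populations
#' @return data.frame with population, nSamples, Ho, He, Fis
#' @export
popSummaryStats <- function(x, panel = NULL) {
    pops <- if (is.null(panel)) populations(x)
            else intersect(populations(panel), populations(x))
    sp <- samplePops(x)
    out <- lapply(pops, function(pk) {
        g <- dosage(x)[, sp == pk, drop = FALSE]
        n <- 2 * rowSums(!is.na(g))
        p <- rowSums(g, na.rm = TRUE) / n
        poly <- !is.na(p) & p > 0 & p < 1 & n >= 2
        ho <- rowMeans(g == 1L, na.rm = TRUE)
        he <- 2 * p * (1 - p) * n / (n - 1)
        Ho <- mean(ho[poly]); He <- mean(he[poly])
        data.frame(population = pk, nSamples = ncol(g),
            Ho = ifelse(any(poly), Ho, 0),
            He = ifelse(any(poly), He, 0),
            Fis = ifelse(any(poly), 1 - Ho / He, NA))
    })
    do.call(rbind, out)
}

#' Candidate-gene association tests per SNP
#'
#' For each SNP: a 2x2 allele-count chi-square test of the pooled
#' resistant versus susceptible classes (switching to Fisher's exact test
#' when an expected cell drops below 1, with a message), and the Pearson
#' correlation between per-population allele frequency and survival.
#' P-values of each family are Benjamini-Hochberg adjusted across SNPs.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param panel a \linkS4class{PopulationPanel}
#' @return data.frame with per-SNP statistics and adjusted p-values
#' @export
candidateGeneAssoc <- function(x, panel) {
    cl <- resistanceClass(panel)
    sp <- samplePops(x)
    if (length(unique(sp[cl[sp] == "R"])) < 2 ||
        length(unique(sp[cl[sp] == "S"])) < 2)
        stop("need at least 2 populations per class")
    g <- dosage(x)
    grpCounts <- function(samp) {
        gs <- g[, samp, drop = FALSE]
        n <- 2 * rowSums(!is.na(gs))
        c1 <- rowSums(gs, na.rm = TRUE)
        cbind(alt = c1, ref = n - c1)
    }
    R <- grpCounts(names(sp)[cl[sp] == "R"])
    S <- grpCounts(names(sp)[cl[sp] == "S"])
    freqs <- popAlleleFreqs(x)
    surv <- survivalProp(panel)[rownames(freqs)]
    nFisher <- 0L
    stats <- lapply(seq_len(nrow(g)), function(i) {
        tab <- rbind(R[i, ], S[i, ])
        chi2 <- NA_real_; pChi <- NA_real_; fisher <- FALSE
        if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
            expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
            if (any(expd < 1)) {
                fisher <- TRUE
                pChi <- stats::fisher.test(tab)$p.value
                chi2 <- NA_real_
            } else {
                ct <- suppressWarnings(stats::chisq.test(tab,
                                                         correct = FALSE))
                chi2 <- unname(ct$statistic); pChi <- ct$p.value
            }
        } else { chi2 <- 0; pChi <- 1 }
        fv <- freqs[, i]
        ok <- !is.na(fv)
        r <- NA_real_; pCor <- NA_real_
        if (sum(ok) >= 3 && sd(fv[ok]) > 0 && sd(surv[ok]) > 0) {
            ct <- stats::cor.test(fv[ok], surv[ok])
            r <- unname(ct$estimate); pCor <- ct$p.value
        }
        data.frame(chi2 = chi2, chisqP = pChi, fisherUsed = fisher,
                   pearsonR = r, corP = pCor)
    })
    res <- do.call(rbind, stats)
    if (any(res$fisherUsed))
        message(sum(res$fisherUsed),
                " SNPs used Fisher's exact test (expected cell < 1)")
    res <- cbind(data.frame(chrom = siteChrom(x), pos = sitePos(x)), res)
    res$chisqPAdj <- p.adjust(res$chisqP, method = "BH")
    res$corPAdj <- p.adjust(res$corP, method = "BH")
    res
}
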
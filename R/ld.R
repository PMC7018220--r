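#' Composite linkage disequilibrium summary for a chromosome
#'
#' Estimates LD between unphased diploid genotypes as the squared Pearson
#' correlation of dosage vectors (the composite, genotype-correlation r^2;
#' appropriate for called genotypes). SNPs are prefiltered to minor-allele
#' frequency >= \code{mafMin} and missing fraction < \code{maxMissing},
#' since rare alleles inflate the variance of LD estimates. Reports the
#' chromosome-wide mean and third quartile over all retained pairs (within
#' \code{maxDist} when finite), per-window mean r^2 over consecutive
#' \code{windowSize}-SNP windows, and elevated-LD spans: maximal runs of
#' consecutive windows whose mean pairwise r^2 exceeds
#' \code{r2Threshold}.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param chrom chromosome to summarise
#' @param mafMin minimum minor-allele frequency (default 0.05)
#' @param maxMissing maximum missing fraction (default 0.2, exclusive)
#' @param maxDist only pair SNPs within this many bp (default Inf)
#' @param windowSize SNPs per window for span detection (default 10; finer
#'   than the diversity windows so that compact elevated-LD blocks resolve)
#' @param r2Threshold elevated-LD threshold (default 0.25)
#' @param regions optional \linkS4class{RegionSet}; adds per-region mean
#'   r^2 among SNPs inside each region
#' @return list with \code{chrom}, \code{nSnps}, \code{meanR2},
#'   \code{q3R2}, \code{windows} (data.frame), \code{spans} (data.frame of
#'   elevated intervals), and optionally \code{regionR2}
#' @export
ldR2 <- function(x, chrom, mafMin = 0.05, maxMissing = 0.2, maxDist = Inf,
                 windowSize = 10, r2Threshold = 0.25, regions = NULL) {
    keep <- siteChrom(x) == chrom
    xd <- x[keep, ]
    xd <- filterSites(xd, mafMin = mafMin, maxMissing = NULL)
    miss <- rowMeans(is.na(dosage(xd)))
    xd <- xd[miss < maxMissing, ]
    g <- t(dosage(xd))
    v <- apply(g, 2, stats::var, na.rm = TRUE)
    xd <- xd[!is.na(v) & v > 0, ]
    g <- t(dosage(xd))
    m <- ncol(g)
    if (m < 2) stop("fewer than 2 qualifying SNPs on ", chrom)
    pos <- sitePos(xd)
    R2 <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))^2
    ut <- upper.tri(R2)
    if (is.finite(maxDist))
        ut <- ut & abs(outer(pos, pos, "-")) <= maxDist
    vals <- R2[ut]
    vals <- vals[!is.na(vals)]
    nw <- m %/% windowSize
    windows <- NULL; spans <- NULL
    if (nw >= 1) {
        wstat <- lapply(seq_len(nw), function(w) {
            idx <- ((w - 1) * windowSize + 1):(w * windowSize)
            sub <- R2[idx, idx]
            data.frame(start = pos[idx[1]], end = pos[idx[length(idx)]],
                       meanR2 = mean(sub[upper.tri(sub)], na.rm = TRUE))
        })
        windows <- do.call(rbind, wstat)
        elev <- windows$meanR2 > r2Threshold
        r <- rle(elev)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
        hi <- which(r$values)
        spans <- if (length(hi)) data.frame(
            start = windows$start[starts[hi]],
            end = windows$end[ends[hi]],
            nWindows = r$lengths[hi]) else
            data.frame(start = numeric(), end = numeric(),
                       nWindows = integer())
    }
    out <- list(chrom = chrom, nSnps = m, meanR2 = mean(vals),
                q3R2 = unname(quantile(vals, 0.75)), windows = windows,
                spans = spans)
    if (!is.null(regions)) {
        gr <- regions(regions)
        siteGr <- SummarizedExperiment::rowRanges(xd)
        out$regionR2 <- vapply(seq_along(gr), function(i) {
            inReg <- which(IRanges::overlapsAny(siteGr, gr[i]))
            if (length(inReg) < 2) return(NA_real_)
            sub <- R2[inReg, inReg]
            mean(sub[upper.tri(sub)], na.rm = TRUE)
        }, 0)
        names(out$regionR2) <- S4Vectors::mcols(gr)$regionId
    }
    out
}
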
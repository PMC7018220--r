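#' @rdname RegionSet-class
#' @export
setMethod("regions", "RegionSet", function(x) x@regions)

#' @export
setMethod("show", "RegionSet", function(object) {
    gr <- object@regions
    cat("RegionSet:", length(gr), "regions\n")
    if (length(gr)) {
        df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
            start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
            id = S4Vectors::mcols(gr)$regionId,
            nOutliers = S4Vectors::mcols(gr)$nOutliers)
        print(head(df, 10))
    }
})

#' Delimit outlier-enriched regions
#'
#' Single-linkage clustering of flagged outlier positions per chromosome:
#' consecutive outliers at most \code{maxGap} apart join a cluster, and
#' clusters with at least \code{minOutliers} members become regions
#' spanning the first to the last member outlier (an algorithmic stand-in
#' for delimiting enriched regions by eye; the endpoints always coincide
#' with member positions).
#'
#' @param outliers an outlier table from \code{\link{resistanceScan}}
#'   (columns chrom, pos, outlier), or a data.frame of chrom/pos of
#'   flagged SNPs
#' @param maxGap maximum within-region gap, bp (default 2e6)
#' @param minOutliers minimum member count (default 5)
#' @return a \linkS4class{RegionSet}
#' @export
delimitRegions <- function(outliers, maxGap = 2e6, minOutliers = 5) {
    df <- if ("outlier" %in% names(outliers))
        outliers[outliers$outlier %in% TRUE, c("chrom", "pos")]
    else outliers[, c("chrom", "pos")]
    params <- list(maxGap = maxGap, minOutliers = minOutliers)
    mkEmpty <- function() {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr)$regionId <- character()
        S4Vectors::mcols(gr)$nOutliers <- integer()
        methods::new("RegionSet", regions = gr, params = params)
    }
    if (!nrow(df)) return(mkEmpty())
    out <- list()
    for (ch in unique(df$chrom)) {
        pos <- sort(df$pos[df$chrom == ch])
        cl <- cumsum(c(1, diff(pos) > maxGap))
        for (k in unique(cl)) {
            p <- pos[cl == k]
            if (length(p) >= minOutliers)
                out[[length(out) + 1L]] <- data.frame(chrom = ch,
                    start = min(p), end = max(p), n = length(p))
        }
    }
    if (!length(out)) return(mkEmpty())
    d <- do.call(rbind, out)
    gr <- GenomicRanges::GRanges(d$chrom,
        IRanges::IRanges(d$start, d$end),
        regionId = sprintf("region%02d", seq_len(nrow(d))),
        nOutliers = d$n)
    methods::new("RegionSet", regions = GenomicRanges::sort(gr),
                 params = params)
}

#' Fraction of outlier SNPs falling inside delimited regions
#'
#' @param outliers outlier table (as for \code{\link{delimitRegions}})
#' @param regionSet a \linkS4class{RegionSet}
#' @return fraction in [0, 1]
#' @export
fractionInRegions <- function(outliers, regionSet) {
    df <- if ("outlier" %in% names(outliers))
        outliers[outliers$outlier %in% TRUE, c("chrom", "pos")]
    else outliers[, c("chrom", "pos")]
    if (!nrow(df)) stop("no outlier SNPs")
    gr <- regions(regionSet)
    if (!length(gr)) return(0)
    snps <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(df$pos, width = 1L))
    mean(IRanges::overlapsAny(snps, gr))
}

# place |lengths| non-overlapping intervals uniformly on the genome;
# plain numeric representation (chrom, start, end) for speed inside
# resampling loops
.placeRandomRegions <- function(lengths, seqlengths, maxTry = 100) {
    chroms <- names(seqlengths)
    n <- length(lengths)
    out <- data.frame(chrom = character(n), start = numeric(n),
                      end = numeric(n))
    lengths <- sort(lengths, decreasing = TRUE)
    for (k in seq_len(n)) {
        L <- lengths[k]
        okChrom <- chroms[seqlengths >= L]
        if (!length(okChrom))
            stop("a region is longer than every chromosome")
        placed <- FALSE
        for (tr in seq_len(maxTry)) {
            ch <- if (length(okChrom) == 1L) okChrom else
                sample(okChrom, 1L, prob = seqlengths[okChrom] - L + 1)
            st <- sample.int(seqlengths[[ch]] - L + 1L, 1L)
            en <- st + L - 1
            prev <- seq_len(k - 1L)
            clash <- any(out$chrom[prev] == ch & out$start[prev] <= en &
                         out$end[prev] >= st)
            if (!clash) {
                out[k, ] <- list(ch, st, en)
                placed <- TRUE
                break
            }
        }
        if (!placed)
            stop("could not place non-overlapping random regions")
    }
    out
}

# count genes (start/end vectors per chromosome) overlapping any of the
# intervals in a placement data.frame
.countOverlapping <- function(geneIdx, placement) {
    hit <- rep(FALSE, length(geneIdx$start))
    for (k in seq_len(nrow(placement))) {
        same <- geneIdx$chrom == placement$chrom[k]
        hit <- hit | (same & geneIdx$start <= placement$end[k] &
                      geneIdx$end >= placement$start[k])
    }
    sum(hit)
}

#' Gene-family enrichment of regions by genome resampling
#'
#' For each family, counts the genes overlapping the observed regions,
#' then builds an empirical null by repeatedly placing the same number of
#' non-overlapping intervals with the observed lengths uniformly on the
#' annotated genome and re-counting. The empirical p-value uses the
#' plus-one correction p = (1 + #\{null >= observed\}) / (nResample + 1),
#' which never reports zero. Caveat retained from the original procedure:
#' resampling interval sizes "does not account well for variation in gene
#' density" along the genome.
#'
#' @param regionSet a \linkS4class{RegionSet}
#' @param genes GRanges with mcols \code{family} (see
#'   \code{\link{readGeneAnnotation}})
#' @param families families to test (default: the four detoxification
#'   families present)
#' @param nResample resampling replicates (default 1000)
#' @param seed integer seed
#' @param seqlengths named chromosome lengths (default: from \code{genes})
#' @return data.frame per family: observed count, null mean/q95, empirical
#'   p, genes per Mb in the observed regions
#' @export
familyEnrichment <- function(regionSet, genes,
        families = setdiff(unique(S4Vectors::mcols(genes)$family),
                           "other"),
        nResample = 1000, seed = 1, seqlengths = NULL) {
    gr <- regions(regionSet)
    if (!length(gr)) stop("empty RegionSet")
    if (is.null(seqlengths)) {
        seqlengths <- GenomeInfoDb::seqlengths(genes)
        if (any(is.na(seqlengths)))
            stop("genes must carry seqlengths (or pass them explicitly)")
    }
    missingChrom <- setdiff(unique(as.character(
        GenomicRanges::seqnames(gr))), names(seqlengths))
    if (length(missingChrom))
        stop("annotation lacks chromosomes: ",
             paste(missingChrom, collapse = ", "))
    fam <- S4Vectors::mcols(genes)$family
    lens <- GenomicRanges::width(gr)
    obs <- vapply(families, function(f)
        sum(IRanges::overlapsAny(genes[fam == f], gr)), 0L)
    famIdx <- lapply(families, function(f) list(
        chrom = as.character(GenomicRanges::seqnames(genes))[fam == f],
        start = GenomicRanges::start(genes)[fam == f],
        end = GenomicRanges::end(genes)[fam == f]))
    names(famIdx) <- families
    set.seed(seed)
    nullCounts <- matrix(0L, nResample, length(families),
                         dimnames = list(NULL, families))
    for (b in seq_len(nResample)) {
        rnd <- .placeRandomRegions(lens, seqlengths)
        for (f in families)
            nullCounts[b, f] <- .countOverlapping(famIdx[[f]], rnd)
    }
    mb <- sum(as.numeric(lens)) / 1e6
    data.frame(family = families,
        observed = unname(obs),
        nullMean = colMeans(nullCounts),
        nullQ95 = apply(nullCounts, 2, quantile, 0.95),
        p = vapply(families, function(f)
            (1 + sum(nullCounts[, f] >= obs[[f]])) / (nResample + 1), 0),
        genesPerMb = unname(obs) / mb, row.names = NULL)
}
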
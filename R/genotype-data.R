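#' Construct a GenotypeData object
#'
#' Assembles the dosage matrix and its site/sample metadata into the central
#' container used by every statistic in the package. Sites are sorted by
#' (chromosome, position); dosages are alternate-allele counts per diploid
#' individual (0, 1, 2) with \code{NA} for missing calls.
#'
#' @param dosage integer matrix, sites x samples, entries in \{0,1,2,NA\}
#' @param chrom character vector of site chromosomes
#' @param pos integer vector of 1-based site positions
#' @param ref,alt single-base reference / alternate alleles per site
#' @param ancestral optional per-site ancestral allele (NA where unknown)
#' @param samples sample identifiers (defaults to dosage colnames)
#' @param populations character vector mapping each sample to a population
#' @param seqlengths optional named vector of chromosome lengths
#' @return a \linkS4class{GenotypeData}
#' @examples
#' g <- GenotypeData(matrix(c(0L, 1L, 2L, 0L), 2), chrom = c("chr1", "chr1"),
#'     pos = c(100L, 200L), ref = c("A", "C"), alt = c("T", "G"),
#'     samples = c("p1_1", "p1_2"), populations = c("p1", "p1"))
#' dosage(g)
#' @export
GenotypeData <- function(dosage, chrom, pos, ref, alt, ancestral = NA,
                         samples = colnames(dosage), populations,
                         seqlengths = NULL) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    nsite <- nrow(dosage)
    if (is.null(samples))
        samples <- paste0("sample", seq_len(ncol(dosage)))
    ancestral <- rep_len(as.character(ancestral), nsite)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(as.integer(pos),
                                                         width = 1L),
        ref = as.character(ref), alt = as.character(alt),
        ancestral = ancestral)
    names(gr) <- paste(chrom, pos, sep = ":")
    o <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
    gr <- gr[o]
    dosage <- dosage[o, , drop = FALSE]
    dimnames(dosage) <- list(names(gr), samples)
    if (!is.null(seqlengths)) {
        lv <- GenomeInfoDb::seqlevels(gr)
        v <- setNames(rep(NA_integer_, length(lv)), lv)
        hit <- intersect(names(seqlengths), lv)
        v[hit] <- as.integer(seqlengths[hit])
        GenomeInfoDb::seqlengths(gr) <- v
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage), rowRanges = gr,
        colData = S4Vectors::DataFrame(population = as.character(populations),
                                       row.names = samples))
    methods::new("GenotypeData", se)
}

#' @rdname GenotypeData
#' @export
setMethod("dosage", "GenotypeData", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' @rdname GenotypeData
#' @export
setMethod("samplePops", "GenotypeData", function(x)
    setNames(as.character(SummarizedExperiment::colData(x)$population),
             colnames(x)))

#' @rdname populations
#' @export
setMethod("populations", "GenotypeData", function(x)
    unique(as.character(SummarizedExperiment::colData(x)$population)))

#' Site chromosome and position accessors
#'
#' @param x a GenotypeData
#' @return \code{siteChrom}: character vector; \code{sitePos}: integer vector
#'   of 1-based positions.
#' @export
siteChrom <- function(x)
    as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(x)))

#' @rdname siteChrom
#' @export
sitePos <- function(x)
    GenomicRanges::start(SummarizedExperiment::rowRanges(x))

#' Ancestral allele per site (NA where unknown)
#' @param x a GenotypeData
#' @export
ancestralAllele <- function(x) {
    a <- S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$ancestral
    as.character(a)
}

#' Derived (non-ancestral) allele count per site for a set of samples
#'
#' Sites whose ancestral allele is missing or matches neither ref nor alt
#' get \code{NA} derived counts.
#'
#' @param x a GenotypeData
#' @param samples sample names or indices (default all)
#' @return list with per-site derived allele count \code{cd} and non-missing
#'   allele count \code{n}
#' @keywords internal
derivedCounts <- function(x, samples = colnames(x)) {
    g <- dosage(x)[, samples, drop = FALSE]
    n <- 2L * rowSums(!is.na(g))
    calt <- rowSums(g, na.rm = TRUE)
    mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(x))
    anc <- as.character(mc$ancestral)
    cd <- ifelse(is.na(anc), NA_real_,
          ifelse(anc == mc$ref, calt,
          ifelse(anc == mc$alt, n - calt, NA_real_)))
    list(cd = cd, n = n)
}

#' @export
setMethod("show", "GenotypeData", function(object) {
    cat("GenotypeData:", nrow(object), "sites x", ncol(object), "samples,",
        length(populations(object)), "populations\n")
    ch <- unique(siteChrom(object))
    cat("  chromosomes:", paste(head(ch, 6), collapse = ", "),
        if (length(ch) > 6) "..." else "", "\n")
})
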
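#' Read a multi-sample VCF of biallelic SNPs into a GenotypeData
#'
#' Parses GT fields with \pkg{vcfR}, keeps biallelic SNPs only, converts
#' genotypes to alternate-allele dosages, and applies the standard site
#' filters: minimum minor-allele frequency and maximum fraction of missing
#' genotype calls. An \code{AA=} INFO key, when present, populates the
#' per-site ancestral allele. The two filters commute, so their order is
#' immaterial.
#'
#' Genotype-level depth filtering (e.g. masking calls with read depth of 5
#' or less) is applied only when a \code{DP} FORMAT field is present and
#' \code{minDepth} is given; otherwise it is skipped with a message, since
#' depth-aware QC belongs upstream of this representation. Two optional
#' site-level filters guard against collapsed paralogs: \code{maxHet} drops
#' sites whose observed heterozygosity exceeds the threshold (0.8 is the
#' conventional default) and \code{maxCovRatio} drops sites whose mean depth
#' exceeds that multiple of the genome-wide mean (conventionally 2).
#'
#' @param path VCF file (plain or bgzipped)
#' @param panel optional \linkS4class{PopulationPanel}; every sample's
#'   population must then appear in the panel
#' @param mafMin minimum minor-allele frequency (default 0.02)
#' @param maxMissing maximum fraction of missing calls per site (default 0.2)
#' @param populations optional named character vector sample -> population;
#'   by default the population is the sample name with a trailing
#'   \code{"_<number>"} stripped
#' @param minDepth optional integer; genotype calls with DP <= minDepth are
#'   set missing when the VCF carries DP
#' @param maxHet optional site filter on observed heterozygosity
#' @param maxCovRatio optional site filter on relative mean depth
#' @return a \linkS4class{GenotypeData}
#' @export
readGenotypeVcf <- function(path, panel = NULL, mafMin = 0.02,
                            maxMissing = 0.2, populations = NULL,
                            minDepth = NULL, maxHet = NULL,
                            maxCovRatio = NULL) {
    .checkVcfLines(path)
    vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
        error = function(e) stop("failed to parse VCF '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    fix <- vcf@fix
    if (is.null(fix) || nrow(fix) == 0L)
        return(.emptyGenotypes(vcf, populations, panel))
    keep <- vcfR::is.biallelic(vcf) &
        nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
    keep[is.na(keep)] <- FALSE
    vcf <- vcf[keep, ]
    fix <- vcf@fix
    if (nrow(fix) == 0L)
        return(.emptyGenotypes(vcf, populations, panel))
    gt <- vcfR::extract.gt(vcf, element = "GT")
    g <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    g[gt %in% c("0/0", "0|0")] <- 0L
    g[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    g[gt %in% c("1/1", "1|1")] <- 2L
    if (!is.null(minDepth)) {
        if ("DP" %in% unlist(strsplit(vcf@gt[1, "FORMAT"], ":"))) {
            dp <- suppressWarnings(
                matrix(as.numeric(vcfR::extract.gt(vcf, element = "DP")),
                       nrow(g), ncol(g)))
            g[!is.na(dp) & dp <= minDepth] <- NA_integer_
            covmean <- rowMeans(dp, na.rm = TRUE)
        } else {
            message("no DP FORMAT field; depth filter skipped")
            covmean <- NULL
        }
    } else covmean <- NULL
    anc <- sub(".*AA=([ACGTacgt]).*", "\\1", fix[, "INFO"])
    anc[!grepl("AA=", fix[, "INFO"] %||% "")] <- NA_character_
    samples <- colnames(g)
    pops <- .samplePopulations(samples, populations)
    if (!is.null(panel)) {
        missing <- setdiff(unique(pops), populations(panel))
        if (length(missing))
            stop("samples map to populations absent from the panel: ",
                 paste(missing, collapse = ", "))
    }
    gd <- GenotypeData(g, chrom = fix[, "CHROM"],
        pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
        alt = fix[, "ALT"], ancestral = anc, samples = samples,
        populations = pops)
    gd <- filterSites(gd, mafMin = mafMin, maxMissing = maxMissing)
    if (!is.null(maxHet)) {
        het <- rowMeans(dosage(gd) == 1L, na.rm = TRUE)
        gd <- gd[!is.na(het) & het <= maxHet, ]
    }
    if (!is.null(maxCovRatio) && !is.null(covmean)) {
        covmean <- covmean[rownames(dosage(gd))]
        gd <- gd[covmean <= maxCovRatio * mean(covmean, na.rm = TRUE), ]
    }
    gd
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.checkVcfLines <- function(path, nMax = 1000L) {
    con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
    on.exit(close(con))
    lines <- readLines(con, n = nMax, warn = FALSE)
    body <- which(!startsWith(lines, "#"))
    for (i in body) {
        if (length(strsplit(lines[i], "\t", fixed = TRUE)[[1]]) < 8L)
            stop("malformed VCF record at line ", i, " of '", path, "'")
    }
    invisible(TRUE)
}

.samplePopulations <- function(samples, populations = NULL) {
    if (!is.null(populations)) {
        p <- populations[samples]
        if (any(is.na(p)))
            stop("no population mapping for samples: ",
                 paste(samples[is.na(p)], collapse = ", "))
        return(unname(p))
    }
    sub("_[0-9]+$", "", samples)
}

.emptyGenotypes <- function(vcf, populations, panel) {
    samples <- setdiff(colnames(vcf@gt), "FORMAT")
    pops <- if (length(samples)) .samplePopulations(samples, populations)
            else character()
    GenotypeData(matrix(integer(), 0L, length(samples)),
        chrom = character(), pos = integer(), ref = character(),
        alt = character(), samples = samples, populations = pops)
}

#' Site filters on a GenotypeData
#'
#' Keeps sites with minor-allele frequency at least \code{mafMin} and
#' missing-call fraction at most \code{maxMissing}. Both are computed from
#' the dosage matrix; applying the two filters in either order gives the
#' same result.
#'
#' @param x a GenotypeData
#' @param mafMin minimum minor allele frequency (NULL to skip)
#' @param maxMissing maximum missing fraction (NULL to skip)
#' @return filtered GenotypeData
#' @export
filterSites <- function(x, mafMin = NULL, maxMissing = NULL) {
    g <- dosage(x)
    keep <- rep(TRUE, nrow(g))
    if (!is.null(maxMissing))
        keep <- keep & rowMeans(is.na(g)) <= maxMissing
    if (!is.null(mafMin)) {
        p <- rowMeans(g, na.rm = TRUE) / 2
        maf <- pmin(p, 1 - p)
        keep <- keep & !is.na(maf) & maf >= mafMin
    }
    x[keep, ]
}

#' Write a GenotypeData as a VCF 4.2 text file
#'
#' Dosages become unphased GT calls (\code{0/0}, \code{0/1}, \code{1/1},
#' \code{./.}); the ancestral allele, when present, is written as an
#' \code{AA=} INFO key so that a round trip preserves it.
#'
#' @param x a GenotypeData
#' @param path output path (plain text)
#' @return the path, invisibly
#' @export
writeGenotypeVcf <- function(x, path) {
    g <- dosage(x)
    gt <- matrix("./.", nrow(g), ncol(g))
    gt[!is.na(g) & g == 0L] <- "0/0"
    gt[!is.na(g) & g == 1L] <- "0/1"
    gt[!is.na(g) & g == 2L] <- "1/1"
    mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(x))
    anc <- as.character(mc$ancestral)
    info <- ifelse(is.na(anc), ".", paste0("AA=", anc))
    header <- c("##fileformat=VCFv4.2",
        "##source=sweepmode",
        "##INFO=<ID=AA,Number=1,Type=Character,Description=\"Ancestral allele\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", colnames(g)), collapse = "\t"))
    body <- if (nrow(g)) paste(siteChrom(x), sitePos(x), ".", mc$ref, mc$alt,
        ".", "PASS", info, "GT",
        apply(gt, 1L, paste, collapse = "\t"), sep = "\t") else character()
    writeLines(c(header, body), path)
    invisible(path)
}

#' Default gene-family keyword configuration
#'
#' Ordered patterns (matched case-insensitively against the concatenated
#' GFF3 attribute text of each gene) mapping to detoxification gene-family
#' labels; the first matching entry wins. GO:0055114
#' (oxidation-reduction) maps to cytochrome P450, GO:0006979 (response to
#' oxidative stress) to glutathione S-transferase; GO:0009635 (response to
#' herbicide) marks detoxification candidates without a family and maps to
#' "other". Replace or reorder freely.
#'
#' @return data.frame with columns \code{pattern} and \code{family}
#' @export
defaultFamilyConfig <- function() {
    data.frame(
        pattern = c("cytochrome P450", "glycosyltransferase",
                    "glutathione s-transferase", "ABC transporter",
                    "GO:0055114", "GO:0006979", "GO:0009635"),
        family = c("cytochrome P450", "glycosyltransferase",
                   "glutathione S-transferase", "ABC transporter",
                   "cytochrome P450", "glutathione S-transferase", "other"),
        stringsAsFactors = FALSE)
}

#' Read gene records from a GFF3 annotation
#'
#' Imports \code{gene} features and assigns each a gene-family label by
#' matching the configured keyword/GO patterns (in configuration order;
#' first match wins) against the gene's attribute text (Name, Note,
#' product, description, Ontology_term). Genes matching nothing are labelled
#' \code{"other"}.
#'
#' @param path GFF3 file
#' @param familyConfig data.frame(pattern, family); see
#'   \code{\link{defaultFamilyConfig}}
#' @return GRanges with mcols \code{geneId} and \code{family}
#' @export
readGeneAnnotation <- function(path, familyConfig = defaultFamilyConfig()) {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
        error = function(e) stop("failed to parse GFF3 '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    gr <- gr[gr$type == "gene"]
    if (!length(gr)) {
        out <- GenomicRanges::GRanges()
        S4Vectors::mcols(out)$geneId <- character()
        S4Vectors::mcols(out)$family <- character()
        return(out)
    }
    mc <- S4Vectors::mcols(gr)
    ids <- if (!is.null(mc$ID)) as.character(mc$ID)
           else paste0("gene", seq_along(gr))
    if (anyNA(ids))
        stop("gene feature without parseable ID near index ",
             which(is.na(ids))[1])
    textCols <- intersect(c("ID", "Name", "Note", "product", "description",
                            "Ontology_term", "gene_family"), colnames(mc))
    txt <- vapply(seq_along(gr), function(i) {
        vals <- unlist(lapply(textCols, function(cl) {
            v <- mc[[cl]][i]
            if (is.list(v) || methods::is(v, "List")) unlist(v) else v
        }), use.names = FALSE)
        paste(vals[!is.na(vals)], collapse = " ")
    }, "")
    fam <- rep("other", length(gr))
    unset <- rep(TRUE, length(gr))
    for (k in seq_len(nrow(familyConfig))) {
        hit <- unset & grepl(familyConfig$pattern[k], txt,
                             ignore.case = TRUE, fixed = FALSE)
        fam[hit] <- familyConfig$family[k]
        unset[hit] <- FALSE
    }
    out <- GenomicRanges::granges(gr)
    S4Vectors::mcols(out)$geneId <- ids
    S4Vectors::mcols(out)$family <- fam
    out
}

#' Write a RegionSet as a BED file
#'
#' BED uses 0-based half-open intervals; the internal 1-based closed
#' representation is converted at this boundary, so a write/read round trip
#' restores the original coordinates exactly. Two extra columns carry the
#' region id and member-outlier count. Overlapping regions on a chromosome
#' elicit a warning but are still written.
#'
#' @param x a RegionSet
#' @param path output path
#' @return the path, invisibly
#' @export
writeRegionsBed <- function(x, path) {
    gr <- regions(x)
    if (length(gr) > length(GenomicRanges::reduce(gr)))
        warning("overlapping regions on the same chromosome")
    lines <- "# sweepmode regions: chrom start end regionId nOutliers"
    if (length(gr))
        lines <- c(lines, paste(as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
            S4Vectors::mcols(gr)$regionId, S4Vectors::mcols(gr)$nOutliers,
            sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname writeRegionsBed
#' @param params delimitation parameters to attach to the returned set
#' @export
readRegionsBed <- function(path, params = list()) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(lines)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr)$regionId <- character()
        S4Vectors::mcols(gr)$nOutliers <- integer()
        return(methods::new("RegionSet", regions = gr, params = params))
    }
    f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    gr <- GenomicRanges::GRanges(f[, 1],
        IRanges::IRanges(as.integer(f[, 2]) + 1L, as.integer(f[, 3])),
        regionId = f[, 4], nOutliers = as.integer(f[, 5]))
    methods::new("RegionSet", regions = gr, params = params)
}
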
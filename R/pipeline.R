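#' Default pipeline configuration
#'
#' A validated list of every tunable the pipeline exposes, with the
#' package's standing defaults: 25-SNP windows, top 1% differentiation
#' score + top 5% |rho| outlier rule, 2-Mb region gap with >= 5 outliers,
#' r^2 > 0.25 elevated-LD threshold, 1000 enrichment resamples, 100
#' randomized groupings, 1000 F_ST bootstraps. A single global seed is
#' expanded deterministically into per-stage seeds.
#'
#' @param ... overrides of the defaults
#' @return a config list
#' @export
runConfig <- function(...) {
    cfg <- list(
        seed = 1L,
        outDir = file.path(tempdir(), "sweepmode-run"),
        input = NULL,            # NULL = simulate the default scenario
        stages = c("simulate", "scan", "regions", "enrich", "windows",
                   "ld", "haplogroups", "converge"),
        windowSize = 25,
        topScore = 0.01,
        topRho = 0.05,
        thinBp = 1000,
        maxGap = 2e6,
        minOutliers = 5,
        r2Threshold = 0.25,
        nResample = 1000,
        nRand = 100,
        nBoot = 1000,
        mafMin = 0.02,
        maxMissing = 0.2,
        convergeStride = 20,
        Ne = 7.5e5,
        r = 1e-7)
    over <- list(...)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
        stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    cfg
}

#' Validate a pipeline configuration
#'
#' Checks every bound and rejects unknown keys, returning a structured
#' list of error messages (empty when valid) rather than raising on the
#' first failure.
#'
#' @param config a config list (see \code{\link{runConfig}})
#' @return character vector of error messages (length 0 when valid)
#' @export
validateConfig <- function(config) {
    errs <- character()
    ref <- runConfig()
    unknown <- setdiff(names(config), names(ref))
    if (length(unknown))
        errs <- c(errs, paste("unknown keys:",
                              paste(unknown, collapse = ", ")))
    chkNum <- function(key, lo, hi, loOpen = FALSE) {
        v <- config[[key]]
        if (is.null(v) || !is.numeric(v) || length(v) != 1 || is.na(v) ||
            v < lo || v > hi || (loOpen && v <= lo))
            errs <<- c(errs, paste0(key, " must lie in ",
                if (loOpen) "(" else "[", lo, ", ", hi, "]"))
    }
    chkNum("windowSize", 1, 1e6, loOpen = FALSE)
    if (is.numeric(config$windowSize) && config$windowSize < 1)
        errs <- c(errs, "windowSize must be >= 1")
    chkNum("topScore", 0, 1, loOpen = TRUE)
    chkNum("topRho", 0, 1, loOpen = TRUE)
    chkNum("thinBp", 1, Inf)
    chkNum("maxGap", 1, Inf)
    chkNum("minOutliers", 1, Inf)
    chkNum("r2Threshold", 0, 1)
    chkNum("nResample", 1, Inf)
    chkNum("nRand", 1, Inf)
    chkNum("nBoot", 1, Inf)
    chkNum("mafMin", 0, 0.5)
    chkNum("maxMissing", 0, 1)
    chkNum("convergeStride", 1, Inf)
    chkNum("Ne", 1, Inf, loOpen = TRUE)
    chkNum("r", 0, 1, loOpen = TRUE)
    if (is.null(config$seed) || !is.numeric(config$seed))
        errs <- c(errs, "seed must be an integer")
    bad <- setdiff(config$stages, runConfig()$stages)
    if (length(bad))
        errs <- c(errs, paste("unknown stages:", paste(bad,
                                                       collapse = ", ")))
    unique(errs)
}

.stageSeed <- function(seed, i) (as.integer(seed) * 97L + i * 1009L) %%
    .Machine$integer.max

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

#' Run the full pipeline
#'
#' Executes the toggled stages in dependency order
#' (simulate -> scan -> regions -> enrich / windows / ld / haplogroups /
#' converge), writing per-stage TSV outputs and a JSON manifest recording
#' the package version, per-stage seeds, input hashes and output files.
#' A failed stage is marked in the manifest and its dependents are
#' skipped. With identical config and seed the numeric outputs are
#' byte-identical across runs.
#'
#' @param config a validated config list (see \code{\link{runConfig}})
#' @param scenario optional pre-built scenario (from
#'   \code{\link{makeDefaultScenario}}); otherwise one is simulated with
#'   the config seed
#' @return the manifest list, invisibly; written to
#'   \code{file.path(outDir, "manifest.json")}
#' @export
runAll <- function(config = runConfig(), scenario = NULL) {
    errs <- validateConfig(config)
    if (length(errs)) stop("invalid config: ", paste(errs,
                                                     collapse = "; "))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(package = "sweepmode",
        version = as.character(utils::packageVersion("sweepmode")),
        seed = config$seed, stages = list())
    ctx <- new.env(parent = emptyenv())
    ctx$scenario <- scenario
    on <- function(st) st %in% config$stages
    ok <- function(st) !is.null(manifest$stages[[st]]) &&
        identical(manifest$stages[[st]]$status, "ok")
    runStage <- function(name, deps, fun) {
        if (!on(name)) return(invisible())
        if (!all(vapply(deps, ok, TRUE))) {
            manifest$stages[[name]] <<- list(status = "skipped",
                reason = "dependency failed or disabled")
            return(invisible())
        }
        res <- tryCatch(list(status = "ok", value = fun()),
            error = function(e) list(status = "failed",
                                     error = conditionMessage(e)))
        manifest$stages[[name]] <<- c(list(status = res$status),
            res[setdiff(names(res), c("status", "value"))],
            if (!is.null(res$value)) res$value)
        invisible()
    }
    runStage("simulate", character(), function() {
        if (is.null(ctx$scenario))
            ctx$scenario <- makeDefaultScenario(seed = .stageSeed(
                config$seed, 1L))
        sc <- ctx$scenario
        vcf <- file.path(config$outDir, "genotypes.vcf")
        writeGenotypeVcf(sc$genotypes, vcf)
        panelPath <- writePanel(sc$panel, file.path(config$outDir,
                                                    "panel.tsv"))
        list(files = c(vcf, panelPath),
             nSnps = nrow(sc$genotypes),
             nSamples = ncol(sc$genotypes),
             inputHash = unname(tools::md5sum(vcf)))
    })
    runStage("scan", "simulate", function() {
        sc <- ctx$scenario
        thin <- thinSnps(sc$genotypes, bpWindow = config$thinBp,
                         seed = .stageSeed(config$seed, 2L))
        message("thinning retained ", nrow(thin), " of ",
                nrow(sc$genotypes), " SNPs")
        ctx$scan <- resistanceScan(thin, sc$panel,
            topScore = config$topScore, topRho = config$topRho)
        f <- .writeTsv(ctx$scan, file.path(config$outDir, "outliers.tsv"))
        list(files = f, nOutliers = sum(ctx$scan$outlier))
    })
    runStage("regions", "scan", function() {
        ctx$regions <- delimitRegions(ctx$scan, maxGap = config$maxGap,
            minOutliers = config$minOutliers)
        f <- file.path(config$outDir, "regions.bed")
        writeRegionsBed(ctx$regions, f)
        list(files = f, nRegions = length(regions(ctx$regions)),
             fractionInRegions = if (sum(ctx$scan$outlier))
                 fractionInRegions(ctx$scan, ctx$regions) else NA)
    })
    runStage("enrich", "regions", function() {
        sc <- ctx$scenario
        if (!length(regions(ctx$regions))) stop("no regions to test")
        enr <- familyEnrichment(ctx$regions, sc$genes,
            nResample = config$nResample,
            seed = .stageSeed(config$seed, 3L),
            seqlengths = sc$seqlengths)
        f <- .writeTsv(enr, file.path(config$outDir, "enrichment.tsv"))
        list(files = f)
    })
    runStage("windows", "simulate", function() {
        sc <- ctx$scenario
        ws <- windowStats(sc$genotypes, sc$panel,
                          windowSize = config$windowSize)
        f <- .writeTsv(ws, file.path(config$outDir, "windows.tsv"))
        list(files = f, nWindows = nrow(ws))
    })
    runStage("ld", "simulate", function() {
        sc <- ctx$scenario
        res <- lapply(unique(siteChrom(sc$genotypes)), function(ch)
            ldR2(sc$genotypes, ch, windowSize = config$windowSize,
                 r2Threshold = config$r2Threshold))
        df <- do.call(rbind, lapply(res, function(r) data.frame(
            chrom = r$chrom, nSnps = r$nSnps, meanR2 = r$meanR2,
            q3R2 = r$q3R2, nSpans = nrow(r$spans))))
        f <- .writeTsv(df, file.path(config$outDir, "ld.tsv"))
        list(files = f)
    })
    runStage("haplogroups", "regions", function() {
        sc <- ctx$scenario
        gr <- regions(ctx$regions)
        if (!length(gr)) stop("no regions for haplotype grouping")
        rows <- lapply(seq_along(gr), function(i) {
            hg <- haplotypeGroups(sc$genotypes, sc$panel, gr[i],
                seed = .stageSeed(config$seed, 4L))
            if (hg$assignment$ambiguous)
                return(data.frame(regionId =
                    S4Vectors::mcols(gr)$regionId[i],
                    population = NA, rProportion = NA))
            data.frame(regionId = S4Vectors::mcols(gr)$regionId[i],
                population = names(hg$assignment$rProportion),
                rProportion = unname(hg$assignment$rProportion))
        })
        f <- .writeTsv(do.call(rbind, rows),
                       file.path(config$outDir, "haplogroups.tsv"))
        list(files = f)
    })
    runStage("converge", "regions", function() {
        sc <- ctx$scenario
        gr <- regions(ctx$regions)
        if (!length(gr)) stop("no regions for convergence testing")
        freqsAll <- popAlleleFreqs(sc$genotypes, sc$panel)
        neutral <- siteChrom(sc$genotypes) %in% c("chr4", "chr5")
        Fhat <- if (any(neutral))
            estimateF(freqsAll[, neutral, drop = FALSE])
        else estimateF(freqsAll)
        nk <- table(samplePops(sc$genotypes))
        nk <- setNames(as.numeric(nk), names(nk))
        cl <- resistanceClass(sc$panel)
        sel <- names(cl)[cl == "R"]
        rows <- lapply(seq_along(gr), function(i) {
            inReg <- IRanges::overlapsAny(
                SummarizedExperiment::rowRanges(sc$genotypes), gr[i])
            freqs <- freqsAll[, inReg, drop = FALSE]
            pos <- sitePos(sc$genotypes)[inReg]
            fits <- convergenceGridSearch(freqs, pos, Fhat, nk, sel,
                grids = list(s = c(0.1, 0.5, 1), g = c(1e-6, 1e-2),
                             t = c(0, 1e3, 1e4), m = c(0.01, 1)),
                stride = config$convergeStride, Ne = config$Ne,
                r = config$r)
            data.frame(regionId = S4Vectors::mcols(gr)$regionId[i],
                model = vapply(fits, function(f) f@model, ""),
                maxRatio = vapply(fits, function(f) f@maxRatio, 0),
                x0 = vapply(fits, function(f) f@mle$x0, 0),
                s = vapply(fits, function(f) f@mle$s, 0))
        })
        f <- .writeTsv(do.call(rbind, rows),
                       file.path(config$outDir, "convergence.tsv"))
        list(files = f)
    })
    files <- unlist(lapply(manifest$stages, function(s) s$files),
                    use.names = FALSE)
    manifest$outputHashes <- as.list(tools::md5sum(files[file.exists(
        files)]))
    jsonlite::write_json(manifest,
        file.path(config$outDir, "manifest.json"), auto_unbox = TRUE,
        pretty = TRUE, digits = NA, force = TRUE)
    invisible(manifest)
}
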
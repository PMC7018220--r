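#' Sweep-model parameter bundles
#'
#' Constructor for \linkS4class{SweepModelParams}. Defaults follow the
#' package's standing study conditions: effective size 7.5e5, population
#' split time 289,000 generations, recombination rate 1e-7 per bp per
#' generation (chosen so that a strong sweep's hitchhiking footprint spans
#' roughly 1-2 Mb, the scale of empirically delimited outlier regions; see
#' the vignette).
#'
#' @param model one of "neutral", "independent", "migration", "standing"
#' @param s selection coefficient in (0, 1]
#' @param g standing frequency in (0, 1) (standing model)
#' @param t standing time in generations (standing model)
#' @param m migration rate in (0, 1] (migration model)
#' @param source source population id (migration model)
#' @param Ne effective population size
#' @param r recombination rate per bp per generation
#' @param x0 selected-site position (bp)
#' @param selectedPops populations under selection
#' @param splitTime population split time in generations
#' @return a \linkS4class{SweepModelParams}
#' @export
sweepParams <- function(model, s = 1, g = 0.01, t = 0, m = 1,
                        source = character(), Ne = 7.5e5, r = 1e-7,
                        x0 = NA_real_, selectedPops = character(),
                        splitTime = 289000) {
    methods::new("SweepModelParams", model = model, s = s, g = g, t = t,
        m = m, source = source, Ne = Ne, r = r, x0 = x0,
        selectedPops = selectedPops, splitTime = splitTime)
}

#' @export
setMethod("show", "SweepModelParams", function(object) {
    cat("SweepModelParams:", object@model, "\n")
    if (object@model != "neutral") {
        cat("  s =", object@s, " Ne =", object@Ne, " r =", object@r,
            " x0 =", object@x0, "\n")
        if (object@model == "standing")
            cat("  g =", object@g, " t =", object@t, "\n")
        if (object@model == "migration")
            cat("  m =", object@m, " source =", object@source, "\n")
        cat("  selected:", paste(object@selectedPops, collapse = ", "), "\n")
    }
})

#' Ancestral-frequency samplers
#'
#' \code{epsUniform} draws the per-site ancestral frequency uniformly on
#' [a, b] (the generator's default, a flat spectrum of common variants
#' mimicking ascertained SNP panels). \code{epsNeutralSFS} draws from a
#' density proportional to 1/eps on [a, b], the frequency spectrum of
#' neutral mutation-drift equilibrium; use it when calibrating
#' frequency-spectrum statistics (Tajima's D, Fay & Wu's H) whose null
#' expectations assume the neutral spectrum.
#'
#' @param a,b support bounds
#' @return a function(n) returning n draws
#' @export
epsUniform <- function(a = 0.05, b = 0.95) {
    force(a); force(b)
    function(n) runif(n, a, b)
}

#' @rdname epsUniform
#' @export
epsNeutralSFS <- function(a = 0.001, b = 0.999) {
    force(a); force(b)
    function(n) a * (b / a)^runif(n)
}

.matSqrt <- function(m) {
    e <- eigen((m + t(m)) / 2, symmetric = TRUE)
    if (min(e$values) < -1e-6)
        stop("coancestry matrix is not positive semi-definite")
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate neutral population allele frequencies under a coancestry matrix
#'
#' For each site an ancestral frequency eps is drawn from
#' \code{epsSampler}; the population frequency vector is multivariate
#' normal with mean eps and covariance eps(1-eps) F, clipped to
#' [0.01, 0.99]. This is the inference model's own distribution (not a
#' coalescent), which makes the generator self-consistent with the
#' composite-likelihood machinery.
#'
#' @param F a \linkS4class{CoancestryMatrix} or K x K matrix
#' @param nSites number of sites
#' @param epsSampler function(n) drawing ancestral frequencies
#' @param seed integer seed
#' @param clip frequency clip range guarding the Gaussian layer (default
#'   [0.01, 0.99]); when calibrating frequency-spectrum statistics, match
#'   it to the sampler support so the boundary carries no atom of clipped
#'   rare variants
#' @return list with \code{freqs} (K x nSites matrix, rownames populations)
#'   and \code{eps} (length nSites)
#' @export
simulateNeutralFreqs <- function(F, nSites, epsSampler = epsUniform(),
                                 seed = 1, clip = c(0.01, 0.99)) {
    stopifnot(nSites >= 1)
    m <- if (methods::is(F, "CoancestryMatrix")) coancestry(F) else F
    K <- nrow(m)
    L <- .matSqrt(m)
    set.seed(seed)
    eps <- epsSampler(nSites)
    z <- matrix(rnorm(K * nSites), K, nSites)
    x <- rep(eps, each = K) + (L %*% z) * rep(sqrt(eps * (1 - eps)), each = K)
    x <- pmin(pmax(x, clip[1]), clip[2])
    dim(x) <- c(K, nSites)
    rownames(x) <- rownames(m)
    list(freqs = x, eps = eps)
}

#' Inject a sweep into simulated allele frequencies
#'
#' Sites within reach of the sweep (hitchhiking probability y >= 1e-6) are
#' redrawn under the sweep-modified covariance structure of
#' \code{\link{modelCovariance}}; distant sites are untouched, so the
#' sweep is local by construction. Two draw schemes are provided:
#' \describe{
#' \item{\code{"haplotype"} (default)}{a latent swept-haplotype allele
#'   A_i ~ Bernoulli(eps) is drawn per selected population with the
#'   model's sharing structure (a single shared allele under migration;
#'   independent alleles under independent mutation; alleles shared with
#'   probability exp(-r d t) each under standing variation, giving the
#'   pairwise covariance exp(-2 r d t)), and the population frequency
#'   becomes the attenuated mixture y A_i + (1 - y) x_i with x_i the
#'   population's neutral frequency. Near the selected site frequencies
#'   genuinely fix (near 0 or 1), as a hard sweep does; the covariance
#'   matches the model exactly in the leading y terms and up to O(F) in
#'   the residual term. The per-population swept haplotype and y values
#'   are attached as \code{attr(freqs, "sweep")} so genotype sampling can
#'   lay the haplotype down as contiguous gamete segments (see
#'   \code{\link{makeDefaultScenario}}).}
#' \item{\code{"gaussian"}}{a multivariate-normal draw with covariance
#'   exactly eps(1-eps) F'(d); the inference model's own distribution,
#'   used for likelihood self-consistency checks. Its marginals spread
#'   rather than fix, so swept sites look less like empirical sweeps.}
#' }
#'
#' @param freqs K x nSites frequency matrix (rownames populations)
#' @param eps per-site ancestral frequencies
#' @param positions per-site bp positions
#' @param params a \linkS4class{SweepModelParams} (x0, model, etc.)
#' @param F the generating \linkS4class{CoancestryMatrix} or matrix
#' @param seed integer seed
#' @param draw \code{"haplotype"} or \code{"gaussian"}
#' @return modified frequency matrix
#' @export
injectSweep <- function(freqs, eps, positions, params, F, seed = 1,
                        draw = c("haplotype", "gaussian")) {
    draw <- match.arg(draw)
    stopifnot(!is.unsorted(positions))
    if (params@model == "neutral") return(freqs)
    if (params@x0 < min(positions) || params@x0 > max(positions))
        warning("selected position x0 lies outside the span of 'positions'")
    K <- nrow(freqs)
    Fm <- if (methods::is(F, "CoancestryMatrix")) coancestry(F) else F
    pops <- rownames(Fm)
    sel <- match(params@selectedPops, pops)
    d <- abs(positions - params@x0)
    # sweepY gives the source-lineage y, the envelope of every model's reach
    ymax <- sweepY(d, params)
    idx <- which(ymax >= 1e-6)
    set.seed(seed)
    Ln <- .matSqrt(Fm)
    nSel <- length(sel)
    if (draw == "haplotype" && length(idx)) {
        # swept haplotypes are drawn once per sweep, so hitchhiked alleles
        # are consistent along the chromosome (real sweeps drag a single
        # haplotype, which is what creates the elevated-LD block):
        # h0 = the ancestral/source haplotype, hOwn = each population's
        # own local haplotype (standing-variation recombination mosaics
        # switch between them site-by-site)
        h0 <- rbinom(length(idx), 1L, eps[idx])
        hOwn <- matrix(rbinom(nSel * length(idx), 1L,
                              rep(eps[idx], each = nSel)), nSel)
        sweepHap <- matrix(NA_integer_, nSel, length(idx))
        yMat <- matrix(NA_real_, nSel, length(idx))
    }
    for (j in seq_along(idx)) {
        i <- idx[j]
        sdv <- sqrt(eps[i] * (1 - eps[i]))
        if (draw == "gaussian") {
            Fp <- modelCovariance(Fm, d[i], params)$Fp
            x <- eps[i] + sdv * as.vector(.matSqrt(Fp) %*% rnorm(K))
        } else {
            x <- freqs[, i]
            # per-population hitchhiking probability
            yv <- rep(ymax[i], nSel)
            if (params@model == "migration") {
                delta <- log(1 / params@m) / params@s
                yv[] <- exp(-params@r * d[i] * (.sweepTau(params) + delta))
                yv[pops[sel] == params@source] <- ymax[i]
            }
            A <- switch(params@model,
                independent = hOwn[, j],
                migration = rep(h0[j], nSel),
                standing = {
                    q <- exp(-params@r * d[i] * params@t)
                    shared <- runif(nSel) < q
                    ifelse(shared, h0[j], hOwn[, j])
                })
            sweepHap[, j] <- A
            yMat[, j] <- yv
            x[sel] <- yv * A + (1 - yv) * x[sel]
        }
        freqs[, i] <- pmin(pmax(x, 0.01), 0.99)
    }
    if (draw == "haplotype" && length(idx)) {
        attr(freqs, "sweep") <- list(idx = idx, hap = sweepHap,
            y = yMat, sel = sel, selectedPops = pops[sel],
            epsIdx = eps[idx])
    }
    freqs
}

# Lay swept haplotypes down as contiguous gamete segments. Each gamete of
# each selected-population individual descends from that population's
# swept haplotype at the selected site and carries it outward until an
# exponential recombination-escape breakpoint (rate r * tau per bp per
# side), beyond which it keeps its neutral allele. The per-site marginal
# carrier probability is exp(-r d tau) = y, identical to the
# frequency-level injection, but alleles are now collinear along the
# chromosome, which is what produces the elevated-LD block and the shared
# multi-locus haplotype of a real hard sweep.
#
# For the migration model the non-selected populations additionally carry
# a *balanced* alternative haplotype at intermediate frequency (each
# gamete descends from it with probability 1/2 at the selected site, with
# the same escape process). This emulates the balanced standing variation
# empirically seen among non-adapted populations at such loci (strongly
# positive Tajima's D / Fay & Wu's H: two mid-frequency haplotype
# classes), and is what gives the susceptible group its own haplotype
# structure in the region.
.sweepMosaicDosages <- function(g, positions, params, sweep, samplePops,
                                seed) {
    set.seed(seed)
    idx <- sweep$idx
    pos <- positions[idx]
    tau <- .sweepTau(params)
    layBlock <- function(gam, hap, rate) {
        lo <- params@x0 - stats::rexp(1, rate)
        hi <- params@x0 + stats::rexp(1, rate)
        inBlock <- pos >= lo & pos <= hi
        gam[inBlock] <- hap[inBlock]
        gam
    }
    splitGametes <- function(dos) {
        g1 <- ifelse(dos == 2L, 1L, ifelse(dos == 0L, 0L,
            rbinom(length(dos), 1L, 0.5)))
        list(g1, dos - g1)
    }
    for (a in seq_along(sweep$selectedPops)) {
        pk <- sweep$selectedPops[a]
        rate <- params@r * tau
        if (params@model == "migration" && pk != params@source)
            rate <- params@r * (tau + log(1 / params@m) / params@s)
        hap <- sweep$hap[a, ]
        for (smp in which(samplePops == pk)) {
            gs <- splitGametes(g[idx, smp])
            g[idx, smp] <- layBlock(gs[[1]], hap, rate) +
                layBlock(gs[[2]], hap, rate)
        }
    }
    if (params@model == "migration") {
        # the non-selected populations segregate two balanced haplotype
        # classes: the (standing) swept haplotype itself and its
        # divergent counterpart, each carried by about half the gametes
        h0 <- sweep$hap[1, ]
        classes <- list(h0, 1L - h0)
        rate <- params@r * tau
        for (smp in which(!(samplePops %in% sweep$selectedPops))) {
            gs <- splitGametes(g[idx, smp])
            for (gam in 1:2)
                gs[[gam]] <- layBlock(gs[[gam]],
                    classes[[1L + rbinom(1L, 1L, 0.5)]], rate)
            g[idx, smp] <- gs[[1]] + gs[[2]]
        }
    }
    g
}

#' Convert population allele frequencies to diploid genotypes
#'
#' Each of \code{nPerPop} individuals per population receives a binomial(2,
#' x) alternate-allele dosage (within-population Hardy-Weinberg). The
#' ancestral allele is recorded as the reference allele, so derived-allele
#' statistics are computable without an outgroup.
#'
#' @param freqs K x nSites matrix (rownames populations)
#' @param positions per-site bp positions
#' @param chrom chromosome name(s) for the sites
#' @param nPerPop diploid individuals per population
#' @param seed integer seed
#' @param seqlengths optional named chromosome lengths
#' @return a \linkS4class{GenotypeData}
#' @export
freqsToGenotypes <- function(freqs, positions, chrom, nPerPop = 10,
                             seed = 1, seqlengths = NULL) {
    if (nPerPop < 1) stop("nPerPop must be >= 1")
    stopifnot(all(freqs >= 0 & freqs <= 1))
    K <- nrow(freqs); nS <- ncol(freqs)
    pops <- rownames(freqs)
    set.seed(seed)
    g <- matrix(NA_integer_, nS, K * nPerPop)
    for (k in seq_len(K)) {
        cols <- (k - 1L) * nPerPop + seq_len(nPerPop)
        g[, cols] <- rbinom(nS * nPerPop, 2L, rep(freqs[k, ], nPerPop))
    }
    samples <- paste(rep(pops, each = nPerPop),
                     sprintf("%02d", rep(seq_len(nPerPop), K)), sep = "_")
    GenotypeData(g, chrom = rep_len(chrom, nS), pos = positions,
        ref = rep("A", nS), alt = rep("T", nS), ancestral = rep("A", nS),
        samples = samples, populations = rep(pops, each = nPerPop),
        seqlengths = seqlengths)
}

#' Build a toy gene annotation with clustered detoxification families
#'
#' Background genes are placed uniformly along each chromosome; designated
#' clusters (e.g. seven tandem glycosyltransferases within ~42 kb) are laid
#' out tandemly, non-overlapping, inside their interval. Gene \code{Note}
#' attributes carry family keywords so that
#' \code{\link{readGeneAnnotation}} reassigns families from the file alone.
#'
#' @param seqlengths named vector of chromosome lengths
#' @param clusters data.frame(chrom, start, end, family, n) of tandem
#'   clusters; NULL or zero rows gives a background-only annotation
#' @param nBackground background genes per chromosome
#' @param familyProbs named sampling probabilities of background families
#' @param geneLength background/cluster gene length (bp)
#' @param seed integer seed
#' @param path optional GFF3 output path
#' @return GRanges with mcols geneId, family (sorted); written to
#'   \code{path} when given
#' @export
makeToyAnnotation <- function(seqlengths, clusters = NULL,
        nBackground = 200,
        familyProbs = c("other" = 0.9, "cytochrome P450" = 0.03,
                        "glycosyltransferase" = 0.03,
                        "ABC transporter" = 0.025,
                        "glutathione S-transferase" = 0.015),
        geneLength = 2000, seed = 1, path = NULL) {
    set.seed(seed)
    chroms <- names(seqlengths)
    grs <- list()
    for (ch in chroms) {
        st <- sort(sample.int(seqlengths[[ch]] - geneLength, nBackground))
        fam <- sample(names(familyProbs), nBackground, replace = TRUE,
                      prob = familyProbs)
        grs[[ch]] <- GenomicRanges::GRanges(factor(ch, levels = chroms),
            IRanges::IRanges(st, width = geneLength), family = fam)
    }
    out <- do.call(c, unname(grs))
    if (!is.null(clusters) && nrow(clusters)) {
        for (i in seq_len(nrow(clusters))) {
            n <- clusters$n[i]
            span <- clusters$end[i] - clusters$start[i]
            pitch <- floor(span / n)
            if (pitch <= geneLength)
                stop("cluster of ", n, " genes does not fit interval ",
                     clusters$chrom[i], ":", clusters$start[i], "-",
                     clusters$end[i])
            st <- clusters$start[i] + (seq_len(n) - 1L) * pitch
            out <- c(out, GenomicRanges::GRanges(
                factor(clusters$chrom[i], levels = chroms),
                IRanges::IRanges(st, width = geneLength),
                family = clusters$family[i]))
        }
    }
    out <- GenomicRanges::sort(out)
    S4Vectors::mcols(out)$geneId <- sprintf("gene%04d", seq_along(out))
    GenomeInfoDb::seqlengths(out) <- seqlengths[GenomeInfoDb::seqlevels(out)]
    if (!is.null(path)) .writeToyGff(out, path)
    out
}

.familyNote <- function(family) {
    ifelse(family == "other", "hypothetical protein",
           paste(family, "family protein"))
}

.writeToyGff <- function(gr, path) {
    lines <- c("##gff-version 3",
        paste0("##sequence-region ", GenomeInfoDb::seqlevels(gr), " 1 ",
               GenomeInfoDb::seqlengths(gr)))
    mc <- S4Vectors::mcols(gr)
    lines <- c(lines, paste(as.character(GenomicRanges::seqnames(gr)),
        "sweepmode", "gene", GenomicRanges::start(gr),
        GenomicRanges::end(gr), ".", "+", ".",
        paste0("ID=", mc$geneId, ";Name=", mc$geneId, ";Note=",
               .familyNote(mc$family)),
        sep = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' Populations of the default scenario
#'
#' Four highly resistant and four susceptible populations with the survival
#' proportions of the study's population-genomics panel (class means 89%
#' and 16%).
#'
#' @return named survival vector
#' @export
scenarioPopulations <- function() {
    c(WG = 0.83, BI = 1, DW = 1, SPC = 0.71,
      SH4 = 0.1, RB = 0.18, HA = 0.15, FL = 0.20)
}

#' Generate the default synthetic scenario
#'
#' Eight populations (4 resistant, 4 susceptible; 10 diploids each) over
#' five 400-Mb chromosomes. Chromosome 1 carries an independent-mutation
#' sweep, chromosome 2 a migration sweep (the analogue of the empirically
#' strongest, haplotype-shared region), chromosome 3 a standing-variation
#' sweep; chromosomes 4 and 5 are neutral and serve as the coancestry
#' estimation panel. Each sweep chromosome gets 400 densely spaced SNPs
#' within +/-2 Mb of the selected site (mimicking targeted re-sequencing)
#' on top of the genome-wide background. A toy annotation places a
#' seven-gene tandem glycosyltransferase cluster (42.3 kb) plus nine
#' cytochrome P450s at the migration sweep and an ABC-transporter cluster
#' at the standing sweep. Sites monomorphic in the sample are dropped.
#'
#' @param seed integer seed (fully determines the dataset)
#' @param nPerPop diploid individuals per population
#' @param nBackground background SNPs per chromosome
#' @param nDense extra SNPs within +/-2 Mb of each selected site
#' @return list with \code{genotypes} (\linkS4class{GenotypeData}),
#'   \code{panel} (\linkS4class{PopulationPanel}), \code{genes} (GRanges),
#'   \code{truth} (generating parameters, F, eps, seed),
#'   \code{seqlengths}
#' @export
makeDefaultScenario <- function(seed = 1, nPerPop = 10, nBackground = 1200,
                                nDense = c(independent = 500, migration = 200,
                                           standing = 500)) {
    surv <- scenarioPopulations()
    pops <- names(surv)
    rPops <- names(surv)[surv > 0.5]
    panel <- suppressWarnings(PopulationPanel(pops, surv, "P",
        nSamples = nPerPop))
    Fm <- defaultCoancestry(pops)
    chroms <- paste0("chr", 1:5)
    seqlengths <- setNames(rep(4e8, 5), chroms)
    x0 <- 2e8
    sweeps <- list(
        chr1 = sweepParams("independent", s = 1, x0 = x0,
            selectedPops = rPops),
        chr2 = sweepParams("migration", s = 1, m = 1, source = "WG",
            x0 = x0, selectedPops = rPops),
        chr3 = sweepParams("standing", s = 1, g = 1e-6, t = 5000,
            x0 = x0, selectedPops = rPops))
    gds <- list(); epsAll <- list()
    for (ci in seq_along(chroms)) {
        ch <- chroms[ci]
        chromSeed <- seed * 100L + ci
        set.seed(chromSeed)
        pos <- sort(sample.int(seqlengths[[ch]], nBackground))
        if (ch %in% names(sweeps)) {
            # targeted panel over the candidate region. Independent and
            # standing sweeps leave a class-level signal only in the
            # narrow core where lineages fix, so their panels tile the
            # +/-80 kb core densely in addition to the +/-2 Mb region;
            # the migration sweep signals across its whole footprint and
            # gets a uniform region panel.
            nD <- nDense[[sweeps[[ch]]@model]]
            dense <- if (sweeps[[ch]]@model == "migration")
                x0 + sample.int(4e6, nD) - 2e6
            else c(x0 + sample.int(4e6, nD %/% 2) - 2e6,
                   x0 + sample.int(1.6e5, nD - nD %/% 2) - 8e4)
            pos <- sort(c(pos, dense))
        }
        sim <- simulateNeutralFreqs(Fm, length(pos), seed = chromSeed + 7L)
        freqs <- sim$freqs
        if (ch %in% names(sweeps)) {
            freqs <- injectSweep(freqs, sim$eps, pos, sweeps[[ch]], Fm,
                                 seed = chromSeed + 13L)
            # genotypes: neutral base dosages, then the swept haplotype
            # laid down as contiguous gamete segments
            gd <- freqsToGenotypes(sim$freqs, pos, ch, nPerPop = nPerPop,
                seed = chromSeed + 29L, seqlengths = seqlengths)
            g <- .sweepMosaicDosages(dosage(gd), pos, sweeps[[ch]],
                attr(freqs, "sweep"), samplePops(gd),
                seed = chromSeed + 37L)
            gds[[ch]] <- GenotypeData(g, chrom = rep(ch, length(pos)),
                pos = pos, ref = rep("A", length(pos)),
                alt = rep("T", length(pos)),
                ancestral = rep("A", length(pos)),
                samples = colnames(gd),
                populations = unname(samplePops(gd)),
                seqlengths = seqlengths)
        } else {
            gds[[ch]] <- freqsToGenotypes(freqs, pos, ch,
                nPerPop = nPerPop, seed = chromSeed + 29L,
                seqlengths = seqlengths)
        }
        epsAll[[ch]] <- sim$eps
    }
    gd <- do.call(.rbindGenotypes, gds)
    # drop sample-monomorphic sites: real panels contain variable SNPs only
    p <- rowMeans(dosage(gd), na.rm = TRUE) / 2
    gd <- gd[p > 0 & p < 1, ]
    clusters <- data.frame(
        chrom = c("chr2", "chr2", "chr3"),
        start = c(x0 - 21150, x0 + 60000, x0 - 30000),
        end = c(x0 + 21150, x0 + 150000, x0 + 30000),
        family = c("glycosyltransferase", "cytochrome P450",
                   "ABC transporter"),
        n = c(7, 9, 4))
    genes <- makeToyAnnotation(seqlengths, clusters, seed = seed + 1000L)
    truth <- list(sweeps = sweeps, F = Fm, eps = epsAll, seed = seed,
                  x0 = x0, selectedPops = rPops)
    list(genotypes = gd, panel = panel, genes = genes, truth = truth,
         seqlengths = seqlengths)
}

.rbindGenotypes <- function(...) {
    parts <- list(...)
    g <- do.call(rbind, lapply(parts, dosage))
    chrom <- unlist(lapply(parts, siteChrom), use.names = FALSE)
    pos <- unlist(lapply(parts, sitePos), use.names = FALSE)
    mc <- lapply(parts, function(p)
        S4Vectors::mcols(SummarizedExperiment::rowRanges(p)))
    sls <- lapply(parts, function(p)
        GenomeInfoDb::seqlengths(SummarizedExperiment::rowRanges(p)))
    sl <- unlist(sls)[!duplicated(unlist(lapply(sls, names)))]
    GenotypeData(g, chrom = chrom, pos = pos,
        ref = unlist(lapply(mc, function(m) m$ref), use.names = FALSE),
        alt = unlist(lapply(mc, function(m) m$alt), use.names = FALSE),
        ancestral = unlist(lapply(mc, function(m) m$ancestral),
                           use.names = FALSE),
        samples = colnames(parts[[1]]),
        populations = unname(samplePops(parts[[1]])),
        seqlengths = sl)
}
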
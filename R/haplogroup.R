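#' Pairwise genetic distance between individuals
#'
#' The count of sites at which two individuals' dosage codes differ, over
#' pairwise-complete sites (computed with \code{ape::dist.gene} under
#' pairwise deletion). A pair sharing no typed site is an error, caught
#' before any embedding.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param region optional GRanges (or \linkS4class{RegionSet} with a
#'   single region) restricting the sites used
#' @return a symmetric \code{dist}-convertible matrix, zero diagonal
#' @export
pairwiseDiff <- function(x, region = NULL) {
    if (!is.null(region)) {
        gr <- if (methods::is(region, "RegionSet")) regions(region)
              else region
        keep <- IRanges::overlapsAny(SummarizedExperiment::rowRanges(x), gr)
        x <- x[keep, ]
    }
    if (nrow(x) < 1) stop("no SNPs in the selected region")
    if (ncol(x) < 2) stop("need at least 2 individuals")
    g <- t(dosage(x))
    shared <- (!is.na(g)) %*% t(!is.na(g))
    if (any(shared == 0))
        stop("some individual pairs share no typed site")
    d <- ape::dist.gene(g, method = "pairwise", pairwise.deletion = TRUE)
    as.matrix(d)
}

#' Classical multidimensional scaling (principal coordinates)
#'
#' Double-centres the squared-distance matrix and embeds the points on the
#' top-k nonnegative-eigenvalue axes scaled by the square roots of the
#' eigenvalues (\code{stats::cmdscale}). Negative eigenvalues are
#' discarded with a message; fewer than k positive eigenvalues produce a
#' lower-dimensional embedding with a warning.
#'
#' @param d distance matrix (symmetric, nonnegative)
#' @param k target dimension (default 2)
#' @return list with \code{points} (n x <=k) and \code{eig}
#' @export
classicalMds <- function(d, k = 2) {
    d <- as.matrix(d)
    stopifnot(isSymmetric(unname(d)), all(d >= 0))
    fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
    nPos <- sum(fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig)))
    if (any(fit$eig < -1e-8))
        message(sum(fit$eig < -1e-8),
                " negative eigenvalues discarded in MDS")
    if (nPos < k)
        warning("only ", nPos, " positive eigenvalues; returning a ",
                nPos, "-dimensional embedding")
    pts <- fit$points[, seq_len(min(k, max(nPos, 1))), drop = FALSE]
    list(points = pts, eig = fit$eig)
}

#' Two-group k-means with multiple restarts
#'
#' Best-of-\code{nInit} k-means (k = 2) by within-cluster sum of squares,
#' deterministic given the seed. Identical points cannot be split and are
#' an error.
#'
#' @param coords numeric matrix of embedded coordinates
#' @param seed integer seed
#' @param nInit random restarts (default 20)
#' @return a \code{stats::kmeans} fit (2 clusters)
#' @export
kmeans2 <- function(coords, seed = 1, nInit = 20) {
    coords <- as.matrix(coords)
    if (nrow(coords) < 2) stop("need at least 2 points")
    if (nrow(unique(coords)) < 2)
        stop("all points identical; no 2-cluster separation exists")
    set.seed(seed)
    stats::kmeans(coords, centers = 2, nstart = nInit)
}

#' Assign clusters to 'R' and 'S' haplotype groups
#'
#' The cluster containing fewer individuals from susceptible populations
#' is deemed the R group (the haplotype group depleted of susceptible
#' individuals); an exact tie flags the whole region as ambiguous. Also
#' reports, per population, the proportion of its individuals carrying
#' the R-group haplotype.
#'
#' @param clusters integer cluster labels (1/2) named by sample, or a
#'   \code{kmeans} fit
#' @param panel a \linkS4class{PopulationPanel}
#' @param samplePops named character vector sample -> population
#' @return list with \code{group} (per-individual R/S/ambiguous),
#'   \code{rProportion} (per population), \code{ambiguous}
#' @export
assignRGroup <- function(clusters, panel, samplePops) {
    cl <- if (inherits(clusters, "kmeans")) clusters$cluster else clusters
    if (length(unique(cl)) != 2) stop("need exactly two clusters")
    classes <- resistanceClass(panel)
    if (anyNA(classes[samplePops]))
        stop("panel lacks class labels for some populations")
    sInCluster <- vapply(sort(unique(cl)), function(k)
        sum(classes[samplePops[names(cl)[cl == k]]] == "S"), 0L)
    if (sInCluster[1] == sInCluster[2]) {
        return(list(group = setNames(rep("ambiguous", length(cl)),
                                     names(cl)),
                    rProportion = NULL, ambiguous = TRUE))
    }
    rCluster <- sort(unique(cl))[which.min(sInCluster)]
    group <- setNames(ifelse(cl == rCluster, "R", "S"), names(cl))
    pops <- unique(unname(samplePops))
    rProp <- vapply(pops, function(pk) {
        s <- names(samplePops)[samplePops == pk]
        mean(group[s] == "R")
    }, 0)
    list(group = group, rProportion = rProp, ambiguous = FALSE)
}

#' Haplotype-group assignment for a genomic region
#'
#' The full distance -> 2-D classical MDS -> k-means -> R/S labelling
#' chain for one region: individuals are clustered on all SNPs in the
#' region and the cluster depleted of susceptible-population individuals
#' is called the R haplotype group.
#'
#' @param x a \linkS4class{GenotypeData}
#' @param panel a \linkS4class{PopulationPanel}
#' @param region GRanges (or single-region \linkS4class{RegionSet})
#' @param seed integer seed for k-means restarts
#' @return list with \code{assignment} (see \code{\link{assignRGroup}}),
#'   \code{mds} coordinates, \code{kmeans} fit, and cluster quality
#'   (within / between sum of squares)
#' @export
haplotypeGroups <- function(x, panel, region = NULL, seed = 1) {
    d <- pairwiseDiff(x, region)
    emb <- classicalMds(d, k = 2)
    km <- kmeans2(emb$points, seed = seed)
    asg <- assignRGroup(km, panel, samplePops(x))
    list(assignment = asg, mds = emb$points, kmeans = km,
         quality = c(withinSS = km$tot.withinss,
                     betweenSS = km$betweenss))
}
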
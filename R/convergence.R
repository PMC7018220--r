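#' Estimate the coancestry (F) matrix from neutral allele frequencies
#'
#' Moment estimator: with x the population frequency vector at a site and
#' x-bar its across-population mean,
#' F-hat_kl = mean over sites of (x_k - x-bar)(x_l - x-bar) / (x-bar (1 - x-bar)).
#' Sites fixed across all populations are skipped. Eigenvalues are clipped
#' at 1e-6 to restore positive semi-definiteness. Because the unknown
#' ancestral frequency is replaced by the sample mean, the estimator
#' recovers the mean-centred projection of the generating matrix (see
#' \code{\link{centerCoancestry}}); downstream composite likelihoods
#' operate in the same centred space, so this is the right plug-in.
#'
#' @param freqs K x nSites matrix of population allele frequencies
#' @return a \linkS4class{CoancestryMatrix}
#' @export
estimateF <- function(freqs) {
    if (ncol(freqs) < 50) stop("need at least 50 neutral sites")
    if (nrow(freqs) < 2) stop("need at least 2 populations")
    xbar <- colMeans(freqs)
    keep <- xbar > 0 & xbar < 1
    x <- freqs[, keep, drop = FALSE]
    xbar <- xbar[keep]
    dev <- sweep(x, 2, xbar)
    w <- 1 / (xbar * (1 - xbar))
    Fhat <- (dev %*% (w * t(dev))) / ncol(x)
    e <- eigen((Fhat + t(Fhat)) / 2, symmetric = TRUE)
    Fhat <- e$vectors %*% (pmax(e$values, 1e-6) * t(e$vectors))
    dimnames(Fhat) <- list(rownames(freqs), rownames(freqs))
    CoancestryMatrix(Fhat)
}

.sweepTau <- function(params) {
    p0 <- if (params@model == "standing") params@g else 1 / (2 * params@Ne)
    log(1 / p0) / params@s
}

#' Hitchhiking probability at a distance from the selected site
#'
#' y = exp(-r d tau), the probability that a neutral lineage at
#' recombination distance r*d from the selected site stays associated with
#' the sweeping haplotype through a sweep of duration tau = log(1/p0)/s
#' generations, where p0 is 1/(2 Ne) for the independent-mutation model and
#' the migration source, and the standing frequency g for the standing
#' model.
#'
#' @param d distance in bp (vectorised)
#' @param params a \linkS4class{SweepModelParams}
#' @return numeric vector of probabilities
#' @export
sweepY <- function(d, params) {
    if (params@model == "neutral") return(rep(0, length(d)))
    if (params@s <= 0) stop("s must be positive")
    stopifnot(all(d >= 0))
    exp(-params@r * d * .sweepTau(params))
}

#' Sweep-modified coancestry and sampling covariance at one site
#'
#' Builds the modified coancestry F'(d) for a site at distance d from the
#' selected position under each convergence model, and optionally the full
#' sampling covariance. Writing y for the hitchhiking probability:
#' \itemize{
#' \item neutral: F' = F.
#' \item independent mutation: each selected population i gets
#'   F'_ii = y^2 + (1 - y^2) F_ii; all other entries unchanged (sweeps
#'   share no lineages across populations).
#' \item migration: recipients use y_i = exp(-r d (tau + delta)) with
#'   delta = log(1/m)/s, the source uses y_c = exp(-r d tau); for selected
#'   i, j (source included) F'_ij = y_i y_j + (1 - y_i y_j) F_ij and
#'   F'_ii = y_i^2 + (1 - y_i^2) F_ii.
#' \item standing variation: with K_s = 1/(2 Ne g),
#'   P_coal = K_s/(K_s + 2 r d) (1 - exp(-(K_s + 2 r d) t)) and
#'   P_through = exp(-(K_s + 2 r d) t); within selected populations
#'   F'_ii = y^2 (P_coal + P_through) + (1 - y^2 (P_coal + P_through)) F_ii,
#'   between selected populations
#'   F'_ij = y^2 exp(-2 r d t) + (1 - y^2 exp(-2 r d t)) F_ij.
#' }
#' At t = 0 the standing model coincides with migration at delta = 0, and
#' every model collapses to neutral as d grows. Entries falling outside
#' [-1, 1] are clipped (estimated, mean-centred F matrices legitimately
#' carry small negative off-diagonals, so clipping at 0 would break the
#' neutral limit).
#'
#' @param F coancestry matrix (matrix or \linkS4class{CoancestryMatrix})
#'   with population dimnames
#' @param d distance in bp from the selected site
#' @param params a \linkS4class{SweepModelParams}
#' @param eps optional ancestral frequency; when supplied together with
#'   \code{nk} the full covariance eps(1-eps) F' + diag(eps(1-eps)/(2 nk))
#'   is returned as \code{Sigma}
#' @param nk optional named vector of diploid sample sizes
#' @return list with \code{Fp}, \code{y}, and (optionally) \code{Sigma}
#' @export
modelCovariance <- function(F, d, params, eps = NULL, nk = NULL) {
    Fm <- if (methods::is(F, "CoancestryMatrix")) coancestry(F) else F
    pops <- rownames(Fm)
    sel <- match(params@selectedPops, pops)
    if (params@model != "neutral" && anyNA(sel))
        stop("selected populations absent from F: ",
             paste(params@selectedPops[is.na(sel)], collapse = ", "))
    Fp <- Fm
    rd <- params@r * d
    y <- sweepY(d, params)
    if (params@model == "independent") {
        Fp[cbind(sel, sel)] <- y^2 + (1 - y^2) * Fm[cbind(sel, sel)]
    } else if (params@model == "migration") {
        tau <- .sweepTau(params)
        delta <- log(1 / params@m) / params@s
        yv <- setNames(rep(exp(-rd * (tau + delta)), length(sel)), pops[sel])
        if (params@source %in% pops[sel])
            yv[params@source] <- exp(-rd * tau)
        else stop("migration source must be one of the selected populations")
        for (a in seq_along(sel)) for (b in seq_len(a)) {
            i <- sel[a]; j <- sel[b]
            yy <- yv[a] * yv[b]
            Fp[i, j] <- Fp[j, i] <- yy + (1 - yy) * Fm[i, j]
        }
        y <- unname(yv[params@source])
    } else if (params@model == "standing") {
        Ks <- 1 / (2 * params@Ne * params@g)
        Pcoal <- Ks / (Ks + 2 * rd) * (1 - exp(-(Ks + 2 * rd) * params@t))
        Pthrough <- exp(-(Ks + 2 * rd) * params@t)
        within <- y^2 * (Pcoal + Pthrough)
        between <- y^2 * exp(-2 * rd * params@t)
        for (a in seq_along(sel)) for (b in seq_len(a)) {
            i <- sel[a]; j <- sel[b]
            if (i == j) Fp[i, i] <- within + (1 - within) * Fm[i, i]
            else Fp[i, j] <- Fp[j, i] <- between + (1 - between) * Fm[i, j]
        }
    }
    nClip <- sum(Fp < -1 | Fp > 1)
    if (nClip) {
        message(nClip, " covariance entries clipped to [-1, 1]")
        Fp <- pmin(pmax(Fp, -1), 1)
    }
    out <- list(Fp = Fp, y = y, d = d)
    if (!is.null(eps) && !is.null(nk)) {
        v <- eps * (1 - eps)
        out$Sigma <- v * Fp + diag(v / (2 * nk[pops]), nrow(Fm))
    }
    out
}

# Projection used throughout: centre the K-vector, then drop the last
# coordinate (rank K-1). Returns the (K-1) x K projection matrix.
.projMatrix <- function(K) {
    C <- diag(K) - matrix(1 / K, K, K)
    C[seq_len(K - 1), , drop = FALSE]
}

# Log-density of the projected, centred frequency deviation at one site.
# A = Fp + diag(1/(2 nk)); the eps(1-eps) scalar factors out of Sigma.
.projLogLik <- function(xc, epsv, A, P) {
    PA <- P %*% A %*% t(P)
    R <- tryCatch(chol(PA), error = function(e) chol(PA + diag(1e-8,
        nrow(PA))))
    z <- backsolve(R, P %*% xc, transpose = TRUE)
    Km1 <- nrow(PA)
    q <- colSums(z^2) / epsv
    -0.5 * (Km1 * log(2 * pi) + Km1 * log(epsv) +
            2 * sum(log(diag(R))) + q)
}

# The sweep modification is linear in a handful of per-site scalars:
# F'(d) = F + sum_k c_k(d) M_k with fixed matrices M_k carrying (1 - F)
# entries over the selected block. Returns the M_k and a function giving
# the c_k(d) row per site; used to evaluate the composite likelihood
# without rebuilding covariances from scratch at every site.
.sweepCovBasis <- function(Fm, params) {
    pops <- rownames(Fm)
    sel <- match(params@selectedPops, pops)
    K <- nrow(Fm)
    zero <- matrix(0, K, K)
    mkD <- function(ix) {
        m <- zero
        m[cbind(ix, ix)] <- 1 - Fm[cbind(ix, ix)]
        m
    }
    mkB <- function(ix, jx) {
        m <- zero
        for (i in ix) for (j in jx) if (i != j) {
            m[i, j] <- 1 - Fm[i, j]
            m[j, i] <- 1 - Fm[j, i]
        }
        m
    }
    tau <- .sweepTau(params)
    r <- params@r
    if (params@model == "independent") {
        list(mats = list(mkD(sel)),
             coefs = function(d) cbind(exp(-2 * r * d * tau)))
    } else if (params@model == "migration") {
        delta <- log(1 / params@m) / params@s
        src <- sel[pops[sel] == params@source]
        rec <- setdiff(sel, src)
        Mrr <- mkD(rec) + mkB(rec, rec)
        Mss <- mkD(src)
        Msr <- mkB(src, rec)
        list(mats = list(Mrr, Mss, Msr),
             coefs = function(d) {
                 yc <- exp(-r * d * tau)
                 yr <- exp(-r * d * (tau + delta))
                 cbind(yr^2, yc^2, yc * yr)
             })
    } else if (params@model == "standing") {
        Ks <- 1 / (2 * params@Ne * params@g)
        tv <- params@t
        list(mats = list(mkD(sel), mkB(sel, sel)),
             coefs = function(d) {
                 rd <- r * d
                 y2 <- exp(-2 * rd * tau)
                 Pc <- Ks / (Ks + 2 * rd) * (1 - exp(-(Ks + 2 * rd) * tv))
                 Pt <- exp(-(Ks + 2 * rd) * tv)
                 cbind(y2 * (Pc + Pt), y2 * exp(-2 * rd * tv))
             })
    } else stop("no sweep basis for model ", params@model)
}

#' Composite log-likelihood of region frequencies under a sweep model
#'
#' For each SNP the ancestral frequency is estimated by the
#' across-population mean; the observed frequency vector is centred by it,
#' projected to the (K-1)-dimensional space orthogonal to the mean
#' direction (the plug-in removes one degree of freedom), and scored
#' against the similarly projected model covariance
#' eps(1-eps) F'(d) + diag(eps(1-eps)/(2 n_k)). Per-SNP log-densities are
#' summed (composite likelihood: SNPs treated as independent, which is
#' valid for ranking models, not for chi-square calibration). Frequencies
#' are clipped to [0.01, 0.99] before evaluation.
#'
#' @param freqs K x nSites matrix of population frequencies (rownames
#'   populations)
#' @param positions per-site bp positions
#' @param x0 candidate selected-site position
#' @param params a \linkS4class{SweepModelParams} (its x0 is ignored in
#'   favour of the explicit argument)
#' @param F coancestry matrix used for the neutral backbone
#' @param nk named vector of diploid sample sizes per population
#' @return scalar composite log-likelihood
#' @export
compositeLoglik <- function(freqs, positions, x0, params, F, nk) {
    if (ncol(freqs) < 1) stop("empty region")
    Fm <- if (methods::is(F, "CoancestryMatrix")) coancestry(F) else F
    K <- nrow(freqs)
    x <- pmin(pmax(freqs, 0.01), 0.99)
    eps <- colMeans(x)
    epsv <- eps * (1 - eps)
    xc <- sweep(x, 2, eps)
    P <- .projMatrix(K)
    noise <- diag(1 / (2 * nk[rownames(Fm)]), K)
    if (params@model == "neutral") {
        A <- Fm + noise
        return(sum(.projLogLik(xc, epsv, A, P)))
    }
    d <- abs(positions - x0)
    basis <- .sweepCovBasis(Fm, params)
    A0p <- P %*% (Fm + noise) %*% t(P)
    matsP <- vapply(basis$mats, function(m) as.vector(P %*% m %*% t(P)),
                    numeric((K - 1)^2))
    cf <- basis$coefs(d)
    z0 <- P %*% xc
    .compositeLoglikCpp(as.vector(A0p), matsP, cf, z0, epsv)
}

#' Default parameter grids for the convergence grid search
#'
#' @return named list of grids for s, g, t, m
#' @export
defaultGrids <- function() {
    list(s = c(0.01, 0.05, 0.1, 0.3, 0.5, 0.65, 0.8, 1),
         g = c(1e-6, 1e-4, 1e-2, 0.1),
         t = c(0, 5, 10, 50, 100, 1e3, 3e3, 1e4),
         m = c(1e-4, 1e-2, 0.1, 1))
}

#' Composite-likelihood grid search over convergence models
#'
#' Evaluates the maximum composite log-likelihood ratio versus the neutral
#' model for the independent-mutation, migration, and standing-variation
#' models over a parameter grid and a set of candidate selected positions
#' (every \code{stride}-th SNP by default). Models are ranked by their
#' maximum ratio.
#'
#' @param freqs K x nSites population frequency matrix for the region
#' @param positions per-site bp positions
#' @param F coancestry matrix (typically \code{\link{estimateF}} output)
#' @param nk named vector of diploid sample sizes
#' @param selectedPops populations under selection
#' @param grids named list of parameter grids (see
#'   \code{\link{defaultGrids}})
#' @param sources candidate migration source populations (default: all
#'   selected populations)
#' @param models models to fit
#' @param stride evaluate every stride-th SNP position as candidate x0
#' @param Ne effective population size
#' @param r recombination rate per bp per generation
#' @return named list of \linkS4class{ConvergenceFit}, ordered by
#'   decreasing maximum ratio, with attribute \code{"neutralLoglik"}
#' @export
convergenceGridSearch <- function(freqs, positions, F, nk, selectedPops,
        grids = defaultGrids(), sources = selectedPops,
        models = c("independent", "migration", "standing"), stride = 1,
        Ne = 7.5e5, r = 1e-7) {
    if (ncol(freqs) < 10) stop("region must contain at least 10 SNPs")
    if (!length(grids)) stop("grids must be non-empty")
    x0s <- positions[seq(1, length(positions), by = stride)]
    ll0 <- compositeLoglik(freqs, positions, NA, sweepParams("neutral"),
                           F, nk)
    fits <- list()
    for (model in models) {
        combos <- switch(model,
            independent = expand.grid(s = grids$s),
            migration = expand.grid(s = grids$s, m = grids$m,
                source = sources, stringsAsFactors = FALSE),
            standing = expand.grid(s = grids$s, g = grids$g, t = grids$t))
        res <- vector("list", nrow(combos) * length(x0s))
        ridx <- 0L
        profile <- setNames(rep(-Inf, length(x0s)), x0s)
        for (ci in seq_len(nrow(combos))) {
            pr <- combos[ci, , drop = FALSE]
            params <- sweepParams(model,
                s = pr$s,
                g = if (!is.null(pr$g)) pr$g else 0.01,
                t = if (!is.null(pr$t)) pr$t else 0,
                m = if (!is.null(pr$m)) pr$m else 1,
                source = if (!is.null(pr$source)) pr$source
                         else character(),
                Ne = Ne, r = r, selectedPops = selectedPops)
            for (xi in seq_along(x0s)) {
                ratio <- compositeLoglik(freqs, positions, x0s[xi],
                    params, F, nk) - ll0
                ridx <- ridx + 1L
                res[[ridx]] <- cbind(pr, x0 = x0s[xi], ratio = ratio,
                                     row.names = NULL)
                profile[xi] <- max(profile[xi], ratio)
            }
        }
        grid <- do.call(rbind, res)
        best <- grid[which.max(grid$ratio), , drop = FALSE]
        fits[[model]] <- methods::new("ConvergenceFit", model = model,
            maxRatio = best$ratio,
            mle = as.list(best[setdiff(names(best), "ratio")]),
            profile = data.frame(pos = x0s, ratio = unname(profile)),
            grid = grid)
    }
    fits <- fits[order(-vapply(fits, function(f) f@maxRatio, 0))]
    attr(fits, "neutralLoglik") <- ll0
    fits
}

#' @export
setMethod("show", "ConvergenceFit", function(object) {
    cat("ConvergenceFit:", object@model, " max log-likelihood ratio =",
        round(object@maxRatio, 2), "\n")
    cat("  MCLE:", paste(names(object@mle),
        vapply(object@mle, function(v) format(v, digits = 4), ""),
        sep = "=", collapse = "  "), "\n")
})

#' Refine the standing-time estimate on a dense grid
#'
#' Re-evaluates the standing-variation model over \code{tGrid} holding the
#' other parameters at their grid-search maximum, and returns the refined
#' estimate. A sweep that is shared through very recent gene flow drives
#' the refined standing time to zero; a genuinely old standing variant
#' keeps it large.
#'
#' @param fit the standing-model \linkS4class{ConvergenceFit}
#' @param freqs,positions,F,nk as in \code{\link{convergenceGridSearch}}
#' @param selectedPops populations under selection
#' @param tGrid candidate standing times (generations)
#' @param Ne,r model constants
#' @return list with \code{tHat} and the per-t log-likelihood ratios
#' @export
refineStandingTime <- function(fit, freqs, positions, F, nk, selectedPops,
        tGrid = 0:10, Ne = 7.5e5, r = 1e-7) {
    if (fit@model != "standing") stop("fit must be a standing-model fit")
    if (!length(tGrid)) stop("tGrid must be non-empty")
    ll0 <- compositeLoglik(freqs, positions, NA, sweepParams("neutral"),
                           F, nk)
    ratios <- vapply(tGrid, function(tv) {
        params <- sweepParams("standing", s = fit@mle$s, g = fit@mle$g,
            t = tv, Ne = Ne, r = r, selectedPops = selectedPops)
        compositeLoglik(freqs, positions, fit@mle$x0, params, F, nk) - ll0
    }, 0)
    list(tHat = tGrid[which.max(ratios)],
         profile = data.frame(t = tGrid, ratio = ratios))
}
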
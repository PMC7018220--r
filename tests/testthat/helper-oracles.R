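# brute-force oracle implementations, independent of the package's code
# paths; used to freeze expected values for the core estimators

# mean pairwise difference over haplotype columns (theta_pi oracle)
oraclePairwisePi <- function(hap) {
    n <- nrow(hap)
    tot <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
        tot <- tot + sum(hap[i, ] != hap[j, ])
    tot / choose(n, 2)
}

# Nei G_ST from first principles
oracleGst <- function(p) {
    hs <- mean(2 * p * (1 - p))
    pbar <- mean(p)
    ht <- 2 * pbar * (1 - pbar)
    if (ht == 0) 0 else 1 - hs / ht
}

# Weir & Cockerham (1984) two-population theta-hat, scalar, written
# directly from the a/b/c component formulas
oracleWC84 <- function(n1, p1, h1, n2, p2, h2) {
    r <- 2
    nbar <- (n1 + n2) / 2
    CV <- ((n1 - nbar)^2 + (n2 - nbar)^2) / ((r - 1) * nbar^2)
    nc <- nbar * (1 - CV * (r - 1) / r)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (pbar <= 0 || pbar >= 1) return(NA_real_)
    max(a / (a + b + cc), 0)
}

# Tajima's D for one window from allele counts, written from the
# published constants
oracleTajimaD <- function(calt, n) {
    seg <- calt > 0 & calt < n
    S <- sum(seg)
    if (S == 0) return(NA_real_)
    thetaPi <- sum(2 * calt * (n - calt) / (n * (n - 1)))
    i <- seq_len(n - 1)
    a1 <- sum(1 / i); a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
    (thetaPi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# unnormalised Fay & Wu's H from derived counts
oracleFayWuH <- function(cd, n) {
    thetaPi <- sum(2 * cd * (n - cd) / (n * (n - 1)))
    thetaH <- sum(2 * cd^2 / (n * (n - 1)))
    thetaPi - thetaH
}

# O(n^2 m) pairwise dosage-difference counter with pairwise deletion
oracleDistLoop <- function(g) {
    n <- nrow(g)
    d <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        ok <- !is.na(g[i, ]) & !is.na(g[j, ])
        d[i, j] <- sum(g[i, ok] != g[j, ok])
    }
    d
}

# classical MDS by hand: double-centred Gram matrix eigendecomposition
oracleMds <- function(d, k = 2) {
    d <- as.matrix(d)
    n <- nrow(d)
    J <- diag(n) - matrix(1 / n, n, n)
    B <- -0.5 * J %*% (d^2) %*% J
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
    keep <- seq_len(k)
    e$vectors[, keep, drop = FALSE] %*%
        diag(sqrt(pmax(e$values[keep], 0)), k)
}

# exhaustive two-cluster minimiser of within-cluster sum of squares
oracleKmeans2 <- function(x) {
    x <- as.matrix(x)
    n <- nrow(x)
    best <- NULL; bestSS <- Inf
    for (mask in 1:(2^(n - 1) - 1)) {
        lab <- as.integer(intToBits(mask))[seq_len(n)] + 1L
        if (length(unique(lab)) < 2) next
        ss <- 0
        for (k in 1:2) {
            xs <- x[lab == k, , drop = FALSE]
            ctr <- colMeans(xs)
            ss <- ss + sum(sweep(xs, 2, ctr)^2)
        }
        if (ss < bestSS) { bestSS <- ss; best <- lab }
    }
    list(labels = best, withinSS = bestSS)
}

# (K-1)-dimensional MVN log-density with explicit determinant and solve
oracleMvnLogLik <- function(xc, Sigma, P) {
    S <- P %*% Sigma %*% t(P)
    z <- P %*% xc
    k <- nrow(S)
    -0.5 * (k * log(2 * pi) + log(det(S)) +
            as.numeric(t(z) %*% solve(S) %*% z))
}

# Benjamini-Hochberg step-up written directly from the definition
oracleBH <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
}
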
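#' Construct a CoancestryMatrix
#'
#' @param mat symmetric K x K numeric matrix with population dimnames
#' @return a \linkS4class{CoancestryMatrix}
#' @export
CoancestryMatrix <- function(mat) {
    mat <- as.matrix(mat)
    if (is.null(rownames(mat)))
        dimnames(mat) <- list(paste0("pop", seq_len(nrow(mat))),
                              paste0("pop", seq_len(nrow(mat))))
    methods::new("CoancestryMatrix", mat = (mat + t(mat)) / 2)
}

#' @rdname CoancestryMatrix
#' @export
setMethod("coancestry", "CoancestryMatrix", function(x) x@mat)

#' @rdname CoancestryMatrix
#' @export
setMethod("populations", "CoancestryMatrix", function(x) rownames(x@mat))

#' @export
setMethod("show", "CoancestryMatrix", function(object) {
    cat("CoancestryMatrix:", nrow(object@mat), "populations\n")
    print(round(object@mat, 4))
})

#' Default coancestry matrix for the bundled eight-population scenario
#'
#' A realistic low-differentiation structure: per-population drift variance
#' 0.1 on the diagonal, background covariance 0.02 between populations, and
#' an elevated 0.08 between the two populations known to exchange recent
#' migrants (WG and SPC). Diagonally dominant, hence positive definite.
#'
#' @param pops population names (default: the scenario's eight)
#' @return a \linkS4class{CoancestryMatrix}
#' @export
defaultCoancestry <- function(pops = names(scenarioPopulations())) {
    K <- length(pops)
    m <- matrix(0.02, K, K, dimnames = list(pops, pops))
    diag(m) <- 0.1
    if (all(c("WG", "SPC") %in% pops)) {
        m["WG", "SPC"] <- m["SPC", "WG"] <- 0.08
    }
    CoancestryMatrix(m)
}

#' Mean-centred projection of a coancestry matrix
#'
#' Applies C F C' with C = I - 11'/K. Allele frequencies carry information
#' only about this projection of F (adding a constant to a row and column
#' of F shifts every population equally and is unobservable), which is why
#' \code{\link{estimateF}} recovers the centred matrix.
#'
#' @param x a CoancestryMatrix or matrix
#' @return matrix of the same dimension
#' @export
centerCoancestry <- function(x) {
    m <- if (methods::is(x, "CoancestryMatrix")) coancestry(x) else x
    K <- nrow(m)
    C <- diag(K) - matrix(1 / K, K, K)
    out <- C %*% m %*% C
    dimnames(out) <- dimnames(m)
    out
}
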
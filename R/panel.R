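#' Construct a PopulationPanel
#'
#' @param pop character population ids
#' @param survival proportion of individuals surviving treatment, in [0, 1]
#' @param usage character vector (comma/semicolon separated flags) or list of
#'   character vectors of usage flags per population
#' @param nSamples optional integer, genotyped samples per population
#' @return a \linkS4class{PopulationPanel}
#' @examples
#' p <- PopulationPanel(c("WG", "SH4"), c(0.83, 0.1), c("E,P", "E,P"))
#' resistanceClass(p)
#' @export
PopulationPanel <- function(pop, survival, usage = "",
                            nSamples = NA_integer_) {
    if (!is.list(usage))
        usage <- strsplit(as.character(usage), "[,;[:space:]]+")
    usage <- lapply(rep_len(usage, length(pop)),
                    function(u) u[nzchar(u)])
    obj <- methods::new("PopulationPanel", pop = as.character(pop),
        survival = as.numeric(survival), usage = usage,
        nSamples = rep_len(as.integer(nSamples), length(pop)))
    if (any(obj@survival == 0.5))
        warning("survival exactly 0.5 classified as 'S' (tie rule): ",
                paste(obj@pop[obj@survival == 0.5], collapse = ", "))
    obj
}

#' @rdname PopulationPanel
#' @param x a PopulationPanel
#' @export
setMethod("populations", "PopulationPanel", function(x) x@pop)

#' @rdname PopulationPanel
#' @export
setMethod("survivalProp", "PopulationPanel", function(x)
    setNames(x@survival, x@pop))

#' @rdname PopulationPanel
#' @export
setMethod("usageFlags", "PopulationPanel", function(x)
    setNames(x@usage, x@pop))

#' @rdname PopulationPanel
#' @export
setMethod("resistanceClass", "PopulationPanel", function(x)
    setNames(ifelse(x@survival > 0.5, "R", "S"), x@pop))

#' @export
setMethod("show", "PopulationPanel", function(object) {
    cl <- resistanceClass(object)
    cat("PopulationPanel:", length(object@pop), "populations (",
        sum(cl == "R"), "R /", sum(cl == "S"), "S )\n")
    df <- data.frame(pop = object@pop, class = cl,
        survival = object@survival,
        usage = vapply(object@usage, paste, "", collapse = ","),
        row.names = NULL)
    print(head(df, 10))
    if (length(object@pop) > 10) cat("  ...\n")
})

#' @rdname PopulationPanel
#' @param i index or population name
#' @export
setMethod("[", "PopulationPanel", function(x, i) {
    if (is.character(i)) i <- match(i, x@pop)
    methods::new("PopulationPanel", pop = x@pop[i], survival = x@survival[i],
        usage = x@usage[i], nSamples = x@nSamples[i])
})

#' Read a population panel from a TSV file
#'
#' Expects columns \code{population}, \code{survival} and optionally
#' \code{usage} (comma-separated flags) and \code{n_samples}. The
#' resistance class is derived from survival (> 0.5 is \code{"R"}); rows are
#' validated and survival outside [0, 1] is an error.
#'
#' @param path TSV file path
#' @return a \linkS4class{PopulationPanel}
#' @export
readPanel <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            comment.char = "#")
    need <- c("population", "survival")
    if (!all(need %in% names(df)))
        stop("panel file must have columns: ", paste(need, collapse = ", "))
    if (any(is.na(df$survival)) ||
        any(df$survival < 0 | df$survival > 1))
        stop("survival values must lie in [0, 1]")
    PopulationPanel(df$population, df$survival,
        usage = if ("usage" %in% names(df)) df$usage else "",
        nSamples = if ("n_samples" %in% names(df)) df$n_samples
                   else NA_integer_)
}

#' Write a population panel to TSV
#' @param panel a PopulationPanel
#' @param path output path
#' @export
writePanel <- function(panel, path) {
    df <- data.frame(population = panel@pop, survival = panel@survival,
        usage = vapply(panel@usage, paste, "", collapse = ","),
        n_samples = panel@nSamples)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Mean survival (percent) over panel rows matching a usage flag and class
#'
#' Averages the survival proportions over populations that carry
#' \code{usageFlag} and whose derived class equals \code{classLabel}, and
#' reports the arithmetic mean as an integer percentage, rounded half-up
#' (88.5 reports as 89).
#'
#' @param panel a PopulationPanel
#' @param usageFlag usage flag to match (e.g. \code{"P"}); \code{NULL}
#'   matches every population
#' @param classLabel \code{"R"} or \code{"S"}
#' @return integer percent
#' @examples
#' p <- PopulationPanel(c("A", "B"), c(0.8, 0.9), "P")
#' panelSurvivalSummary(p, "P", "R")  # 85
#' @export
panelSurvivalSummary <- function(panel, usageFlag, classLabel) {
    keep <- resistanceClass(panel) == classLabel
    if (!is.null(usageFlag))
        keep <- keep & vapply(panel@usage, function(u) usageFlag %in% u, TRUE)
    if (!any(keep))
        stop("no populations match usage '", usageFlag, "' and class '",
             classLabel, "'")
    # round half-up (base round() is banker's rounding)
    floor(mean(panel@survival[keep]) * 100 + 0.5)
}
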
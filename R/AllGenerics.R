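#' @rdname GenotypeData
#' @param x a GenotypeData object
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypeData
#' @export
setGeneric("samplePops", function(x) standardGeneric("samplePops"))

#' Population identifiers held by an object
#' @param x a PopulationPanel, CoancestryMatrix or GenotypeData
#' @return character vector of population ids
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname PopulationPanel
#' @export
setGeneric("resistanceClass", function(x) standardGeneric("resistanceClass"))

#' @rdname PopulationPanel
#' @export
setGeneric("survivalProp", function(x) standardGeneric("survivalProp"))

#' @rdname PopulationPanel
#' @export
setGeneric("usageFlags", function(x) standardGeneric("usageFlags"))

#' @rdname CoancestryMatrix
#' @param x a CoancestryMatrix
#' @export
setGeneric("coancestry", function(x) standardGeneric("coancestry"))

#' @rdname RegionSet-class
#' @param x a RegionSet
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
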
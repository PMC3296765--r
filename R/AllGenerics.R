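#' @importFrom BiocGenerics counts
NULL

#' @rdname CountSet-accessors
#' @export
setGeneric("sampleData", function(x, ...) standardGeneric("sampleData"))

#' @rdname CountSet-accessors
#' @export
setGeneric("totalCounts", function(x, ...) standardGeneric("totalCounts"))

#' @rdname OrthologSet-accessors
#' @export
setGeneric("referenceSpecies",
           function(x, ...) standardGeneric("referenceSpecies"))

#' @rdname OrthologSet-accessors
#' @export
setGeneric("referenceGenes", function(x, ...) standardGeneric("referenceGenes"))

#' @rdname OrthologSet-accessors
#' @export
setGeneric("orthologSpecies",
           function(x, ...) standardGeneric("orthologSpecies"))

#' @rdname OrthologSet-accessors
#' @export
setGeneric("coreGenes", function(x, ...) standardGeneric("coreGenes"))

#' @rdname OrthologSet-accessors
#' @export
setGeneric("orthologId",
           function(x, genes, species, ...) standardGeneric("orthologId"))

#' @rdname sigmaFor
#' @export
setGeneric("sigmaFor",
           function(object, genes, species, ...) standardGeneric("sigmaFor"))
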
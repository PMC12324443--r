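#' @rdname XLinkSet-accessors
#' @export
setGeneric("xlRecords", function(x) standardGeneric("xlRecords"))

#' @rdname StructureModel-accessors
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))

#' @rdname StructureModel-accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname StructureModel-accessors
#' @export
setGeneric("chainProteins", function(x) standardGeneric("chainProteins"))

#' @rdname StructureModel-accessors
#' @export
setGeneric("chainProteins<-",
           function(x, value) standardGeneric("chainProteins<-"))

#' @rdname StructureModel-accessors
#' @export
setGeneric("caCoords", function(x, chain = NULL) standardGeneric("caCoords"))

#' @rdname EnsembleReport-accessors
#' @export
setGeneric("ensembleSummary", function(x) standardGeneric("ensembleSummary"))

#' @rdname EnsembleReport-accessors
#' @export
setGeneric("linkVerdicts", function(x) standardGeneric("linkVerdicts"))

#' @rdname EnsembleReport-accessors
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))
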
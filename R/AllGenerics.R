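#' @rdname pseudotime
#' @export
setGeneric("pseudotime", function(x) standardGeneric("pseudotime"))

#' @rdname pseudotime
#' @export
setGeneric("pseudotime<-", function(x, value) standardGeneric("pseudotime<-"))

#' @rdname selectedCells
#' @export
setGeneric("selectedCells", function(x) standardGeneric("selectedCells"))

#' @rdname selectedCells
#' @export
setGeneric("selectedCells<-",
           function(x, value) standardGeneric("selectedCells<-"))

#' @rdname exprMatrix
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname geneNames
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' @rdname nBins
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname binMatrix
#' @export
setGeneric("binMatrix", function(x) standardGeneric("binMatrix"))

#' @rdname teValues
#' @export
setGeneric("teValues", function(x) standardGeneric("teValues"))

#' @rdname edges
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
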
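#' @rdname Portfolio-class
#' @param x the object.
#' @export
setGeneric("nSolvers", function(x) standardGeneric("nSolvers"))

#' @rdname Portfolio-class
#' @export
setGeneric("solverIds", function(x) standardGeneric("solverIds"))

#' @rdname PerformanceTable-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname PerformanceTable-class
#' @param criterion \code{"strict"} or \code{"relaxed"}.
#' @export
setGeneric("successMatrix",
           function(x, criterion = c("strict", "relaxed"))
             standardGeneric("successMatrix"))

#' @rdname PerformanceTable-class
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname PerformanceTable-class
#' @export
setGeneric("portfolio", function(x) standardGeneric("portfolio"))

#' @rdname PerformanceTable-class
#' @export
setGeneric("instanceIds", function(x) standardGeneric("instanceIds"))

#' @rdname PerformanceTable-class
#' @export
setGeneric("scoringConfig", function(x) standardGeneric("scoringConfig"))

#' @rdname InstanceSet-class
#' @export
setGeneric("proteinEmbeddings",
           function(x) standardGeneric("proteinEmbeddings"))

#' @rdname InstanceSet-class
#' @export
setGeneric("ligandEmbeddings",
           function(x) standardGeneric("ligandEmbeddings"))

#' @rdname InstanceSet-class
#' @export
setGeneric("embeddingDims", function(x) standardGeneric("embeddingDims"))

#' @rdname DockSelector-class
#' @export
setGeneric("nParams", function(x) standardGeneric("nParams"))
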
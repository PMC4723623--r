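#' @name berrynet-generics
#' @title Generics defined by berrynet
#' @description Accessor and coercion generics for the package's S4 classes.
#' @param object,x an object of the documented class.
#' @param ... further arguments for methods.
NULL

#' @rdname berrynet-generics
#' @export
setGeneric("processing", function(object) standardGeneric("processing"))

#' @rdname berrynet-generics
#' @export
setGeneric("stageOrder", function(object) standardGeneric("stageOrder"))

#' @rdname berrynet-generics
#' @export
setGeneric("intensityMatrix", function(object, ...) standardGeneric("intensityMatrix"))

#' @rdname berrynet-generics
#' @export
setGeneric("metaboliteAnnotation", function(object) standardGeneric("metaboliteAnnotation"))

#' @rdname berrynet-generics
#' @export
setGeneric("sampleAnnotation", function(object) standardGeneric("sampleAnnotation"))

#' @rdname berrynet-generics
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname berrynet-generics
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname berrynet-generics
#' @export
setGeneric("nodeDegrees", function(object) standardGeneric("nodeDegrees"))

#' @rdname berrynet-generics
#' @export
setGeneric("asIgraph", function(object, ...) standardGeneric("asIgraph"))

#' @rdname berrynet-generics
#' @export
setGeneric("correlationMatrix", function(object) standardGeneric("correlationMatrix"))

#' @rdname berrynet-generics
#' @export
setGeneric("adjustedPValues", function(object) standardGeneric("adjustedPValues"))
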
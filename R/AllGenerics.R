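#' @include utils.R
NULL

#' Accessors for dbnCrosstalk objects
#'
#' Standard accessor generics for the S4 classes of the package.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))

#' @rdname accessors
#' @export
setGeneric("seriesContext", function(x) standardGeneric("seriesContext"))

#' @rdname accessors
#' @export
setGeneric("seriesCondition", function(x) standardGeneric("seriesCondition"))

#' @rdname accessors
#' @export
setGeneric("stimAssignment", function(x) standardGeneric("stimAssignment"))

#' @rdname accessors
#' @export
setGeneric("nTimePoints", function(x) standardGeneric("nTimePoints"))

#' @rdname accessors
#' @export
setGeneric("molecules", function(x) standardGeneric("molecules"))

#' @rdname accessors
#' @export
setGeneric("parentSets", function(x) standardGeneric("parentSets"))

#' @rdname accessors
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))

#' @rdname accessors
#' @export
setGeneric("modelStructure", function(x) standardGeneric("modelStructure"))

#' @rdname accessors
#' @export
setGeneric("transitionCPTs", function(x) standardGeneric("transitionCPTs"))

#' @rdname accessors
#' @export
setGeneric("initialCPTs", function(x) standardGeneric("initialCPTs"))

#' @rdname accessors
#' @export
setGeneric("posteriorArray", function(x) standardGeneric("posteriorArray"))
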
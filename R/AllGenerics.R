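#' @rdname ResponseMatrix-class
#' @param object,x a \code{ResponseMatrix}.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("personIds", function(x) standardGeneric("personIds"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))

#' @rdname ResponseMatrix-class
#' @export
setGeneric("nCategories", function(x) standardGeneric("nCategories"))

#' @rdname RSMParams-class
#' @param x an \code{RSMParams} or \code{RSMFit}.
#' @export
setGeneric("itemDifficulties", function(x) standardGeneric("itemDifficulties"))

#' @rdname RSMParams-class
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname RSMFit-class
#' @param x an \code{RSMFit}.
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @rdname RSMFit-class
#' @export
setGeneric("personMeasures", function(x) standardGeneric("personMeasures"))
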
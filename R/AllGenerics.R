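#' @rdname accessors
#' @export
setGeneric("cellType", function(object) standardGeneric("cellType"))

#' @rdname accessors
#' @export
setGeneric("parentType", function(object) standardGeneric("parentType"))

#' @rdname accessors
#' @export
setGeneric("classifierFeatures",
           function(object) standardGeneric("classifierFeatures"))

#' @rdname accessors
#' @export
setGeneric("probThreshold", function(object) standardGeneric("probThreshold"))

#' @rdname accessors
#' @export
setGeneric("classifierModel",
           function(object) standardGeneric("classifierModel"))

#' @rdname accessors
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(object) standardGeneric("cellTypes"))

#' @rdname accessors
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))

#' @rdname accessors
#' @export
setGeneric("bestGuess", function(object) standardGeneric("bestGuess"))

#' @rdname accessors
#' @export
setGeneric("probabilities", function(object) standardGeneric("probabilities"))

#' Predict calibrated cell-type probabilities
#'
#' @param classifier a [CellClassifier-class].
#' @param m an [ExpressionMatrix-class] (normalized, or raw with
#'   `auto_normalize = TRUE`).
#' @param ... further arguments passed to methods.
#' @return Named numeric vector: one probability in (0, 1) per cell.
#' @export
setGeneric("predictProbability",
           function(classifier, m, ...) standardGeneric("predictProbability"))
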
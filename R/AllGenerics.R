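#' Gene names of an object
#'
#' @param x a \linkS4class{MaskMatrix} or \linkS4class{TokenTransformer}.
#' @return character vector of gene identifiers, in model order.
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))

#' Token (gene-set) names of an object
#'
#' @param x a \linkS4class{MaskMatrix}, \linkS4class{TokenTransformer} or
#'   \linkS4class{AttentionEmbedding}.
#' @return character vector of gene-set names, in token order.
#' @export
setGeneric("tokenNames", function(x) standardGeneric("tokenNames"))

#' Gene sets stored in a collection
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @return named list of character vectors.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' Cell-type classes known to a model
#'
#' @param x a \linkS4class{TokenTransformer} or
#'   \linkS4class{CellTypePrediction}.
#' @return character vector of class labels ("Unknown" excluded).
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Per-epoch training history
#'
#' @param x a \linkS4class{TokenTransformer}.
#' @return data.frame with one row per epoch: learning rate, train loss and
#'   accuracy, validation loss and accuracy.
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' Predicted labels of a query
#'
#' @param x a \linkS4class{CellTypePrediction}.
#' @return character vector, one call per cell (may include "Unknown").
#' @export
setGeneric("predictedLabels",
    function(x) standardGeneric("predictedLabels"))

#' Class probability matrix of a query
#'
#' @param x a \linkS4class{CellTypePrediction}.
#' @return numeric matrix (cells x classes), rows summing to 1.
#' @export
setGeneric("classProbs", function(x) standardGeneric("classProbs"))
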
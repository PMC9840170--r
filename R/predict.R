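#' Predict cell types for a query dataset
#'
#' Transfers the reference labels to query cells: each cell receives the
#' argmax class of its softmax probability vector, except that cells whose
#' maximum probability falls below \code{cutoff} (default 0.95) are called
#' \code{"Unknown"} — the mechanism behind novel-cell-type discovery. Ties
#' are broken deterministically by label order. Query cells are aligned to
#' the reference gene vocabulary by name and normalized exactly as the
#' reference was.
#'
#' @param model a trained \linkS4class{TokenTransformer}.
#' @param query a \code{SingleCellExperiment} or cells-by-genes matrix.
#' @param cutoff Unknown-calling probability threshold in [0, 1]; 0
#'   disables Unknown calls. Defaults to the model's configured cutoff.
#' @param chunkSize cells per forward chunk; results are independent of
#'   chunking.
#' @return a \linkS4class{CellTypePrediction}.
#' @export
predictCellTypes <- function(model, query, cutoff = NULL,
                             chunkSize = 1024L) {
    stopifnot(is(model, "TokenTransformer"))
    if (is.null(cutoff)) cutoff <- model@config$unknownCutoff
    if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
    fw <- modelForward(model, query, chunkSize = chunkSize)
    probs <- fw$probabilities
    top <- max.col(probs, ties.method = "first")
    maxProb <- probs[cbind(seq_len(nrow(probs)), top)]
    predicted <- model@labels[top]
    predicted[maxProb < cutoff] <- "Unknown"
    new("CellTypePrediction", probabilities = probs, predicted = predicted,
        maxProb = maxProb, cutoff = cutoff)
}

#' Attention embedding of a query dataset
#'
#' Runs the model forward and returns the interpretable cell embedding: for
#' each cell, the final attention block's class-token attention over the k
#' pathway tokens, averaged across heads. The class-token-to-itself share
#' is excluded, so rows sum to at most 1.
#'
#' @inheritParams predictCellTypes
#' @return an \linkS4class{AttentionEmbedding}.
#' @export
attentionEmbedding <- function(model, query, chunkSize = 1024L) {
    stopifnot(is(model, "TokenTransformer"))
    fw <- modelForward(model, query, chunkSize = chunkSize)
    new("AttentionEmbedding", values = fw$attention)
}

#' @describeIn predictedLabels per-cell calls.
#' @export
setMethod("predictedLabels", "CellTypePrediction", function(x) x@predicted)

#' @describeIn classProbs the cells x classes probability matrix.
#' @export
setMethod("classProbs", "CellTypePrediction", function(x) x@probabilities)

#' @describeIn classLabels classes the prediction was made over.
#' @export
setMethod("classLabels", "CellTypePrediction",
    function(x) colnames(x@probabilities))

#' @describeIn tokenNames tokens (columns) of the embedding.
#' @export
setMethod("tokenNames", "AttentionEmbedding",
    function(x) colnames(x@values))

#' Attention score matrix
#'
#' @param x an \linkS4class{AttentionEmbedding}.
#' @return the cells x tokens numeric matrix.
#' @export
attnValues <- function(x) {
    stopifnot(is(x, "AttentionEmbedding"))
    x@values
}

#' @export
#' @method as.matrix AttentionEmbedding
as.matrix.AttentionEmbedding <- function(x, ...) x@values

setMethod("show", "CellTypePrediction", function(object) {
    tab <- sort(table(object@predicted), decreasing = TRUE)
    cat(sprintf(
        "CellTypePrediction: %d cells, %d classes, cutoff %.2f\n",
        nrow(object@probabilities), ncol(object@probabilities),
        object@cutoff))
    cat("  calls:", paste(sprintf("%s (%d)", names(tab), tab),
        collapse = ", "), "\n")
})

setMethod("show", "AttentionEmbedding", function(object) {
    cat(sprintf("AttentionEmbedding: %d cells x %d tokens\n",
        nrow(object@values), ncol(object@values)))
})
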
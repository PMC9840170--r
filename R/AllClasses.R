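#' @import methods
#' @importFrom Matrix Matrix colSums rowSums t
NULL

#' Named collection of gene sets
#'
#' Holds named gene sets (pathways, regulons) as parsed from a GMT file or
#' produced by the simulator. Gene identifiers are stored as given; matching
#' against expression data is case-insensitive throughout the package.
#'
#' @slot sets named list of character vectors, one per gene set.
#' @slot provenance character scalar recording where the sets came from
#'   (file path, \code{"random"}, or \code{"simulated"}).
#'
#' @seealso [readGMT()], [buildMask()]
#' @export
setClass("GeneSetCollection",
    representation(sets = "list", provenance = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    if (length(object@sets) == 0L)
        msg <- c(msg, "collection contains no gene sets")
    nm <- names(object@sets)
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
        msg <- c(msg, "every gene set must be named")
    else if (anyDuplicated(nm))
        msg <- c(msg, "gene set names must be unique")
    if (any(lengths(object@sets) == 0L))
        msg <- c(msg, "every gene set must be non-empty")
    if (length(msg)) msg else TRUE
})

#' Binary gene-by-token mask matrix
#'
#' The membership matrix M (genes in rows, gene sets / tokens in columns)
#' that gates the learnable embedding weights: a gene can only contribute to
#' a token representing a gene set it belongs to.
#'
#' @slot mask sparse binary \linkS4class{Matrix} (genes x sets) with gene
#'   names as rownames and set names as colnames.
#' @slot provenance character scalar.
#' @slot params list of the filtering parameters used to build the mask.
#'
#' @seealso [buildMask()], [randomMask()], [geneNames()], [tokenNames()]
#' @export
setClass("MaskMatrix",
    representation(mask = "Matrix", provenance = "character",
        params = "list"))

setValidity("MaskMatrix", function(object) {
    m <- object@mask
    msg <- character()
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "mask must carry gene rownames and set colnames")
    v <- m@x
    if (length(v) && !all(v %in% c(0, 1)))
        msg <- c(msg, "mask entries must be 0 or 1")
    if (ncol(m) < 1L)
        msg <- c(msg, "mask must retain at least one gene set")
    if (ncol(m) && any(Matrix::colSums(m) < 1))
        msg <- c(msg, "every retained set must contain at least one gene")
    if (length(msg)) msg else TRUE
})

#' Pathway-token attention model
#'
#' A trained (or freshly initialized) masked-embedding transformer. All
#' learnable arrays live in \code{params}; the effective embedding weights
#' are kept exactly zero off-mask at all times.
#'
#' @slot mask \linkS4class{MaskMatrix} gating the embedding layer.
#' @slot params list of parameter arrays (masked embedding, class token,
#'   attention blocks, feed-forward and classifier weights).
#' @slot labels character vector of cell-type classes, in training order.
#' @slot config list of architecture hyperparameters (see [modelConfig()]).
#' @slot history data.frame of per-epoch training metrics (possibly empty).
#'
#' @seealso [trainModel()], [predictCellTypes()], [attentionEmbedding()]
#' @export
setClass("TokenTransformer",
    representation(mask = "MaskMatrix", params = "list",
        labels = "character", config = "list", history = "data.frame"))

setValidity("TokenTransformer", function(object) {
    msg <- character()
    cfg <- object@config
    if (is.null(cfg$m) || is.null(cfg$H))
        msg <- c(msg, "config must define m and H")
    else if (cfg$m %% cfg$H != 0L)
        msg <- c(msg, "number of heads H must divide embedding dimension m")
    if (length(object@labels) && anyDuplicated(object@labels))
        msg <- c(msg, "class labels must be unique")
    if ("Unknown" %in% object@labels)
        msg <- c(msg, "'Unknown' is reserved and cannot be a training class")
    if (length(msg)) msg else TRUE
})

#' Attention embedding of cells
#'
#' Cells-by-tokens matrix of class-token attention scores: the head-averaged
#' post-softmax attention of the class token over each pathway token, taken
#' from the final attention block. Entries lie in [0, 1] and each cell's row
#' sums to at most 1 (the class-token-to-itself share is excluded).
#'
#' @slot values numeric matrix (cells x tokens) with cell ids as rownames
#'   and token (gene-set) names as colnames.
#' @export
setClass("AttentionEmbedding", representation(values = "matrix"))

setValidity("AttentionEmbedding", function(object) {
    v <- object@values
    msg <- character()
    if (is.null(colnames(v)))
        msg <- c(msg, "attention embedding must carry token colnames")
    if (length(v) && (min(v) < -1e-8 || max(v) > 1 + 1e-8))
        msg <- c(msg, "attention scores must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Cell-type predictions for a query dataset
#'
#' @slot probabilities numeric matrix (cells x classes) of softmax
#'   probabilities; rows sum to 1.
#' @slot predicted character vector of per-cell calls: a training class, or
#'   \code{"Unknown"} when the maximum probability falls below the cutoff.
#' @slot maxProb numeric vector of per-cell maximum probabilities.
#' @slot cutoff numeric scalar used for Unknown calling.
#' @export
setClass("CellTypePrediction",
    representation(probabilities = "matrix", predicted = "character",
        maxProb = "numeric", cutoff = "numeric"))

setValidity("CellTypePrediction", function(object) {
    msg <- character()
    p <- object@probabilities
    if (nrow(p) != length(object@predicted) ||
        nrow(p) != length(object@maxProb))
        msg <- c(msg, "probabilities, predicted and maxProb disagree on cells")
    if (length(p) && any(abs(rowSums(p) - 1) > 1e-5))
        msg <- c(msg, "probability rows must sum to 1")
    if (length(msg)) msg else TRUE
})
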
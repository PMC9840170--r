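#' Preprocess an attention embedding
#'
#' Mirrors the standard scRNA-seq preprocessing applied to attention
#' scores before downstream analysis: per-cell scaling to a fixed total
#' (default 10,000), \code{log(1 + x)}, then PCA over all tokens. The
#' principal components feed neighbor-graph construction for clustering.
#'
#' @param a an \linkS4class{AttentionEmbedding} or non-negative
#'   cells-by-tokens matrix.
#' @param sizeFactor per-cell total (default 1e4).
#' @param nPCs number of principal components (default 50, capped at
#'   \code{k - 1} tokens and \code{cells - 1}).
#' @return list with \code{processed} (normalized log matrix) and
#'   \code{pcs} (cells x nPCs principal-component scores).
#' @export
preprocessAttention <- function(a, sizeFactor = 1e4, nPCs = 50L) {
    v <- if (is(a, "AttentionEmbedding")) attnValues(a) else as.matrix(a)
    if (min(v) < 0) stop("attention scores must be non-negative")
    processed <- .normalizeMatrix(v, sizeFactor)
    npc <- max(1L, min(nPCs, ncol(v) - 1L, nrow(v) - 1L))
    pcs <- stats::prcomp(processed, center = TRUE,
        scale. = FALSE)$x[, seq_len(npc), drop = FALSE]
    rownames(pcs) <- rownames(v)
    list(processed = processed, pcs = pcs)
}

#' Signature attentions of cell groups
#'
#' One-vs-rest two-sided Wilcoxon rank-sum (Mann-Whitney U) test per token
#' per group, on library-size-normalized and log-transformed attention
#' scores, with Benjamini-Hochberg adjustment applied within each group
#' across tokens. Tokens are ranked within each group by the normal-deviate
#' rank-sum statistic (positive = enriched in the group).
#'
#' @param a an \linkS4class{AttentionEmbedding} or cells-by-tokens matrix.
#' @param groups per-cell group labels (cell types or clusters).
#' @param sizeFactor per-cell total used in preprocessing (default 1e4).
#' @param adjust \code{"per-group"} (default) applies BH within each
#'   group's k tokens; \code{"global"} adjusts across all tests at once.
#' @return a data.frame with one row per (group, token): \code{statistic}
#'   (z-scored U), \code{p_value}, \code{p_adj}, \code{direction} (+1
#'   enriched / -1 depleted), \code{rank} within the group.
#' @export
rankAttentions <- function(a, groups, sizeFactor = 1e4,
                           adjust = c("per-group", "global")) {
    adjust <- match.arg(adjust)
    v <- if (is(a, "AttentionEmbedding")) attnValues(a) else as.matrix(a)
    groups <- as.character(groups)
    if (length(groups) != nrow(v))
        stop("groups must have one entry per cell")
    tab <- table(groups)
    if (length(tab) < 2L) stop("need at least 2 groups")
    if (any(tab < 2L) || any(length(groups) - tab < 2L))
        stop("every group and its complement need at least 2 cells")
    x <- suppressWarnings(preprocessAttention(v,
        sizeFactor = sizeFactor))$processed
    tokens <- colnames(v)
    if (is.null(tokens)) tokens <- sprintf("token%d", seq_len(ncol(v)))
    res <- do.call(rbind, lapply(names(tab), function(g) {
        ing <- groups == g
        n1 <- sum(ing); n2 <- sum(!ing)
        out <- data.frame(group = g, token = tokens,
            statistic = NA_real_, p_value = NA_real_)
        for (j in seq_len(ncol(x))) {
            xs <- x[ing, j]; ys <- x[!ing, j]
            wt <- suppressWarnings(stats::wilcox.test(xs, ys,
                alternative = "two.sided"))
            U <- unname(wt$statistic)
            # normal-deviate form of U with tie correction
            r <- rank(c(xs, ys))
            ties <- table(r)
            sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) -
                sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
            z <- if (sigma2 > 0) (U - n1 * n2 / 2) / sqrt(sigma2) else 0
            out$statistic[j] <- z
            out$p_value[j] <- if (sigma2 > 0) wt$p.value else 1
        }
        out
    }))
    res$p_adj <- if (adjust == "per-group") {
        stats::ave(res$p_value, res$group,
            FUN = function(p) stats::p.adjust(p, "BH"))
    } else stats::p.adjust(res$p_value, "BH")
    res$direction <- ifelse(res$statistic >= 0, 1L, -1L)
    res$rank <- stats::ave(-res$statistic, res$group,
        FUN = function(s) rank(s, ties.method = "first"))
    rownames(res) <- NULL
    res
}

#' Sub-cluster cells on their attention embedding
#'
#' Selects the cells of interest, re-preprocesses their attention scores
#' alone (library-size normalization, log1p, PCA), builds a k-nearest-
#' neighbor graph on the principal components and partitions it with the
#' Louvain modularity algorithm at the given resolution (default 0.3).
#'
#' @param a an \linkS4class{AttentionEmbedding} or cells-by-tokens matrix.
#' @param cells optional logical/integer/character index of the cell
#'   subset (default: all cells); at least 10 cells.
#' @param resolution Louvain resolution parameter (default 0.3).
#' @param nNeighbors neighbors per cell in the graph (default 15).
#' @param nPCs principal components used (default 50, capped).
#' @param seed integer seed; the same seed reproduces the same clustering.
#' @return integer cluster labels named by cell id.
#' @export
subclusterCells <- function(a, cells = NULL, resolution = 0.3,
                            nNeighbors = 15L, nPCs = 50L, seed = 1L) {
    v <- if (is(a, "AttentionEmbedding")) attnValues(a) else as.matrix(a)
    if (!is.null(cells)) v <- v[cells, , drop = FALSE]
    n <- nrow(v)
    if (n < 10L) stop("sub-clustering needs at least 10 cells")
    pcs <- suppressWarnings(preprocessAttention(v, nPCs = nPCs))$pcs
    kn <- min(nNeighbors, n - 1L)
    d <- as.matrix(stats::dist(pcs))
    edges <- do.call(rbind, lapply(seq_len(n), function(i) {
        nb <- order(d[i, ])[2:(kn + 1L)]
        cbind(i, nb)
    }))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    cl <- .withSeed(seed,
        igraph::cluster_louvain(g, resolution = resolution))
    out <- as.integer(igraph::membership(cl))
    names(out) <- rownames(v)
    out
}

#' Gene importance for a pathway token
#'
#' Traces a token's signal back to genes: the importance of gene i for
#' token j is the mean over the m embedding dimensions of the absolute
#' masked embedding weight \code{|W'[i, j, ]|}. Off-mask genes have
#' importance exactly zero and are omitted from the ranking.
#'
#' @param state a trained \linkS4class{TokenTransformer}.
#' @param token a token (gene-set) name known to the model.
#' @return a data.frame of member genes sorted by decreasing
#'   \code{importance}.
#' @export
geneImportance <- function(state, token) {
    stopifnot(is(state, "TokenTransformer"))
    toks <- tokenNames(state)
    j <- match(token, toks)
    if (is.na(j)) stop("unknown token: ", token)
    k <- length(toks)
    m <- state@config$m
    W <- state@params$Wemb[, (seq_len(m) - 1L) * k + j, drop = FALSE]
    imp <- rowMeans(abs(W))
    member <- as.vector(maskValues(state@mask)[, j]) != 0
    df <- data.frame(gene = geneNames(state)[member],
        importance = imp[member])
    df <- df[order(-df$importance, df$gene), ]
    rownames(df) <- NULL
    df
}
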
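#' Dataset-difficulty statistics
#'
#' Four scalar characteristics that predict how hard a reference/query
#' label-transfer task is: dataset size on a log10 scale, the number of
#' cell types, the Shannon entropy of the reference label distribution,
#' and the Kullback-Leibler divergence between reference and query label
#' distributions — the strongest (negative) correlate of transfer accuracy.
#'
#' @name datasetMetrics
NULL

#' @describeIn datasetMetrics log10 of the number of cells.
#' @param x a \code{SingleCellExperiment}, a cells-by-genes matrix, or a
#'   cell count.
#' @return a numeric scalar.
#' @export
logSize <- function(x) {
    n <- if (is(x, "SummarizedExperiment")) ncol(x)
        else if (is.matrix(x)) nrow(x)
        else as.numeric(x)
    if (length(n) != 1L || is.na(n) || n < 1)
        stop("need at least one cell")
    log10(n)
}

# Normalize labels/counts/proportions to a proportion vector.
.asProportions <- function(p) {
    if (is.character(p) || is.factor(p)) p <- table(as.character(p))
    p <- unclass(p)
    if (any(p < 0)) stop("negative proportions")
    s <- sum(p)
    if (s <= 0) stop("empty distribution")
    p / s
}

#' @describeIn datasetMetrics Shannon entropy of a label distribution, in
#'   bits: \code{-sum(p * log2(p))} with \code{0 * log(0) = 0}. Zero for a
#'   single class, \code{log2(nc)} for a uniform distribution over
#'   \code{nc} classes.
#' @param p reference label distribution: a vector of labels, counts, or
#'   proportions.
#' @export
shannonEntropy <- function(p) {
    p <- .asProportions(p)
    p <- p[p > 0]
    -sum(p * log2(p))
}

#' @describeIn datasetMetrics Kullback-Leibler divergence
#'   \code{sum(p * log2(p / q))} in bits of the query label distribution
#'   \code{q} from the reference distribution \code{p}. Distributions are
#'   aligned on the union of their (named) labels; a pseudo-count is added
#'   to both and they are renormalized, so labels absent from the query
#'   yield a large finite rather than infinite divergence. Non-negative;
#'   zero iff the smoothed distributions are equal.
#' @param q query label distribution (labels, counts, or proportions).
#' @param pseudo additive smoothing constant (default 1e-9).
#' @export
klDivergence <- function(p, q, pseudo = 1e-9) {
    if ((is.character(p) || is.factor(p)) &&
        (is.character(q) || is.factor(q))) {
        lev <- sort(unique(c(as.character(p), as.character(q))))
        p <- table(factor(as.character(p), levels = lev))
        q <- table(factor(as.character(q), levels = lev))
    }
    p <- .asProportions(p)
    q <- .asProportions(q)
    if (!is.null(names(p)) && !is.null(names(q))) {
        lev <- union(names(p), names(q))
        p <- ifelse(is.na(match(lev, names(p))), 0, p[match(lev, names(p))])
        q <- ifelse(is.na(match(lev, names(q))), 0, q[match(lev, names(q))])
    }
    if (length(p) != length(q))
        stop("p and q must cover the same label set (name them to align)")
    p <- (p + pseudo) / sum(p + pseudo)
    q <- (q + pseudo) / sum(q + pseudo)
    sum(p * log2(p / q))
}

#' @describeIn datasetMetrics all four statistics for a reference/query
#'   pair, as a one-row data.frame with columns \code{log_size},
#'   \code{n_types}, \code{entropy} and \code{d_kl}.
#' @param ref labeled reference \code{SingleCellExperiment}.
#' @param query labeled query \code{SingleCellExperiment}.
#' @param labelKey colData column holding labels (default \code{"label"}).
#' @param pseudo smoothing constant passed to the KL divergence.
#' @export
datasetStats <- function(ref, query, labelKey = "label", pseudo = 1e-9) {
    rl <- as.character(SummarizedExperiment::colData(ref)[[labelKey]])
    ql <- as.character(SummarizedExperiment::colData(query)[[labelKey]])
    if (!length(rl) || !length(ql)) stop("labels missing")
    data.frame(log_size = logSize(ref),
        n_types = length(unique(rl)),
        entropy = shannonEntropy(rl),
        d_kl = klDivergence(rl, ql, pseudo = pseudo))
}
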
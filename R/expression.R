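#' Load an expression matrix
#'
#' Reads a cells-by-genes expression table into a
#' \link[SingleCellExperiment]{SingleCellExperiment} (genes in rows, cells in
#' columns, counts in the \code{"counts"} assay). Two on-disk formats are
#' supported:
#' \describe{
#'   \item{CSV}{cells in rows, genes in columns, first column = cell id;
#'     non-gene metadata columns (e.g. the label column) are moved to
#'     \code{colData}. Use \code{transpose = TRUE} for genes-in-rows CSVs.}
#'   \item{MatrixMarket directory}{\code{matrix.mtx} (genes x cells) plus
#'     \code{features.tsv} and \code{barcodes.tsv}; an optional
#'     \code{obs.csv} (first column = barcode) supplies per-cell metadata.}
#' }
#' Raw counts are accepted; negative entries are rejected.
#'
#' @param path CSV file or MatrixMarket triplet directory.
#' @param labelKey optional name of the per-cell metadata column holding
#'   cell-type labels; stored as \code{colData(x)$label}.
#' @param batchKey optional metadata column holding batch assignments;
#'   stored as \code{colData(x)$batch} (never consumed by the model).
#' @param transpose for CSV input, set \code{TRUE} when genes are in rows.
#' @return a \code{SingleCellExperiment} with a \code{"counts"} assay.
#' @export
loadExpression <- function(path, labelKey = NULL, batchKey = NULL,
                           transpose = FALSE) {
    if (dir.exists(path)) {
        x <- .loadMTXDir(path)
    } else if (file.exists(path)) {
        x <- .loadCSV(path, transpose = transpose)
    } else stop("no such file or directory: ", path)
    counts <- x$counts
    if (min(counts) < 0)
        stop("expression matrix contains negative entries")
    genes <- rownames(counts)
    if (anyDuplicated(tolower(genes)))
        stop("duplicate gene names: ",
            paste(head(unique(genes[duplicated(tolower(genes))]), 10),
                collapse = ", "))
    cd <- x$meta
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = if (is.null(cd)) S4Vectors::DataFrame(
            row.names = colnames(counts)) else cd)
    for (key in c(labelKey, batchKey)) {
        if (!key %in% colnames(SummarizedExperiment::colData(sce)))
            stop("metadata column not found: ", key)
    }
    if (!is.null(labelKey))
        sce$label <- as.character(SummarizedExperiment::colData(sce)[[
            labelKey]])
    if (!is.null(batchKey))
        sce$batch <- as.character(SummarizedExperiment::colData(sce)[[
            batchKey]])
    sce
}

.loadCSV <- function(path, transpose = FALSE) {
    df <- as.data.frame(data.table::fread(path, header = TRUE))
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
    numeric_cols <- vapply(df, is.numeric, logical(1))
    meta <- NULL
    if (any(!numeric_cols)) {
        meta <- S4Vectors::DataFrame(df[, !numeric_cols, drop = FALSE])
        df <- df[, numeric_cols, drop = FALSE]
    }
    m <- as.matrix(df)
    rownames(m) <- ids
    if (transpose) {
        counts <- m  # genes already in rows
        if (!is.null(meta)) stop(
            "metadata columns are only supported for cells-in-rows CSVs")
    } else {
        counts <- t(m)
        if (!is.null(meta)) rownames(meta) <- ids
    }
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("cell%d", seq_len(ncol(counts)))
    if (anyDuplicated(colnames(counts)))
        stop("duplicate cell ids in ", path)
    list(counts = counts, meta = meta)
}

.loadMTXDir <- function(path) {
    mtx <- file.path(path, "matrix.mtx")
    feats <- file.path(path, "features.tsv")
    if (!file.exists(feats)) feats <- file.path(path, "genes.tsv")
    bcs <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, feats, bcs))
        if (!file.exists(f)) stop("missing MatrixMarket component: ", f)
    m <- as.matrix(Matrix::readMM(mtx))
    rownames(m) <- data.table::fread(feats, header = FALSE)[[1L]]
    colnames(m) <- data.table::fread(bcs, header = FALSE)[[1L]]
    meta <- NULL
    obs <- file.path(path, "obs.csv")
    if (file.exists(obs)) {
        od <- as.data.frame(data.table::fread(obs, header = TRUE))
        meta_df <- od[, -1L, drop = FALSE]
        rownames(meta_df) <- as.character(od[[1L]])
        meta <- S4Vectors::DataFrame(meta_df[colnames(m), , drop = FALSE])
    }
    list(counts = m, meta = meta)
}

#' Library-size normalize and log-transform
#'
#' Scales each cell to a fixed total (\code{sizeFactor}, default 10,000) and
#' applies \code{log(1 + x)}, writing the result to the \code{"logcounts"}
#' assay. All-zero cells are left at zero with a warning. This is the
#' default model-input transformation and is also the convention used for
#' attention-embedding preprocessing.
#'
#' @param x a \code{SingleCellExperiment} with a \code{"counts"} assay, or a
#'   plain cells-by-genes matrix.
#' @param sizeFactor target per-cell total (default 1e4).
#' @return the input with normalized values (\code{"logcounts"} assay for a
#'   SingleCellExperiment; a matrix in, matrix out).
#' @export
normalizeCells <- function(x, sizeFactor = 1e4) {
    if (is(x, "SummarizedExperiment")) {
        counts <- t(as.matrix(SummarizedExperiment::assay(x, "counts")))
        ln <- .normalizeMatrix(counts, sizeFactor)
        SummarizedExperiment::assay(x, "logcounts") <- t(ln)
        return(x)
    }
    .normalizeMatrix(as.matrix(x), sizeFactor)
}

.normalizeMatrix <- function(counts, sizeFactor) {
    if (min(counts) < 0) stop("negative entries in expression matrix")
    tot <- rowSums(counts)
    zero <- tot == 0
    if (any(zero))
        warning(sum(zero), " all-zero cell(s) left at zero")
    tot[zero] <- 1
    log1p(counts * (sizeFactor / tot))
}

#' Align an expression object to a gene vocabulary
#'
#' Reorders genes to the model vocabulary by name (case-insensitive).
#' Vocabulary genes missing from the data are zero-filled — the masked
#' embedding then treats them as unmeasured — and extra genes are dropped.
#' The fraction of vocabulary genes found is recorded in
#' \code{metadata(x)$overlap} (or \code{attr(x, "overlap")} for a matrix);
#' an overlap below 10\% aborts, since almost-disjoint gene spaces signal a
#' species or identifier-type mismatch.
#'
#' @param x a \code{SingleCellExperiment} or a cells-by-genes matrix.
#' @param vocabulary character vector of gene identifiers (model order).
#' @return the input re-indexed to \code{vocabulary}.
#' @export
alignToVocabulary <- function(x, vocabulary) {
    vocabulary <- as.character(vocabulary)
    .checkVocabulary(vocabulary)
    if (is(x, "SummarizedExperiment")) {
        hit <- match(tolower(vocabulary), tolower(rownames(x)))
        overlap <- mean(!is.na(hit))
        .checkOverlap(overlap)
        assays <- lapply(SummarizedExperiment::assays(x), function(a) {
            a <- as.matrix(a)
            out <- matrix(0, length(vocabulary), ncol(a),
                dimnames = list(vocabulary, colnames(a)))
            out[!is.na(hit), ] <- a[hit[!is.na(hit)], , drop = FALSE]
            out
        })
        out <- SingleCellExperiment::SingleCellExperiment(assays = assays,
            colData = SummarizedExperiment::colData(x))
        S4Vectors::metadata(out)$overlap <- overlap
        return(out)
    }
    x <- as.matrix(x)
    hit <- match(tolower(vocabulary), tolower(colnames(x)))
    overlap <- mean(!is.na(hit))
    .checkOverlap(overlap)
    out <- matrix(0, nrow(x), length(vocabulary),
        dimnames = list(rownames(x), vocabulary))
    out[, !is.na(hit)] <- x[, hit[!is.na(hit)], drop = FALSE]
    attr(out, "overlap") <- overlap
    out
}

.checkOverlap <- function(overlap) {
    if (overlap < 0.10)
        stop(sprintf(paste0("only %.1f%% of vocabulary genes found in the ",
            "data; gene spaces are almost disjoint (species or identifier ",
            "mismatch?)"), 100 * overlap))
    invisible(TRUE)
}

#' Write per-cell predictions as CSV
#'
#' Emits one row per cell: cell id, predicted label, maximum probability,
#' then one column per training class probability.
#'
#' @param x a \linkS4class{CellTypePrediction}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writePredictions <- function(x, path) {
    stopifnot(is(x, "CellTypePrediction"))
    df <- data.frame(cell_id = rownames(x@probabilities),
        predicted_label = x@predicted,
        max_probability = x@maxProb,
        x@probabilities, check.names = FALSE)
    data.table::fwrite(df, path)
    invisible(path)
}

# Model-ready cells x genes matrix from an expression object: normalized
# when requested (default), aligned to the model vocabulary.
.modelInput <- function(x, vocabulary, normalize = TRUE,
                        sizeFactor = 1e4) {
    if (is(x, "SummarizedExperiment")) {
        if (normalize &&
            !"logcounts" %in% SummarizedExperiment::assayNames(x))
            x <- normalizeCells(x, sizeFactor)
        a <- if (normalize) "logcounts" else "counts"
        m <- t(as.matrix(SummarizedExperiment::assay(x, a)))
    } else {
        m <- as.matrix(x)
        if (normalize) m <- .normalizeMatrix(m, sizeFactor)
    }
    alignToVocabulary(m, vocabulary)
}
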
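#' Read gene sets from a GMT file
#'
#' Parses the tab-separated MSigDB dialect: one set per line, fields are the
#' set name, a description, then member genes. Trailing tabs and CRLF line
#' endings are tolerated. When a gene vocabulary is supplied each set is
#' restricted to genes present in it (case-insensitive match) and sets
#' emptied by the restriction are dropped.
#'
#' @param path path to a GMT file.
#' @param vocabulary optional character vector of gene identifiers to
#'   restrict the sets to.
#' @return a \linkS4class{GeneSetCollection}.
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines(c("S1\tdesc\tA\tB", "S2\tdesc\tB\tC"), gmt)
#' readGMT(gmt, vocabulary = c("A", "B", "C"))
#' @export
readGMT <- function(path, vocabulary = NULL) {
    if (!file.exists(path))
        stop("GMT file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("\r$", "", lines)
    keep <- nzchar(trimws(lines))
    lines <- lines[keep]
    lineno <- which(keep)
    if (!length(lines))
        stop("GMT file is empty: ", path)
    sets <- vector("list", length(lines))
    nm <- character(length(lines))
    for (i in seq_along(lines)) {
        fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        fields <- fields[nzchar(fields)]
        if (length(fields) < 3L)
            stop("malformed GMT line ", lineno[i],
                ": fewer than 3 fields (name, description, genes...)")
        nm[i] <- fields[1L]
        sets[[i]] <- unique(fields[-c(1L, 2L)])
    }
    if (anyDuplicated(nm))
        stop("duplicate gene set names in GMT: ",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
    names(sets) <- nm
    if (!is.null(vocabulary)) {
        voc <- tolower(vocabulary)
        sets <- lapply(sets, function(g) g[tolower(g) %in% voc])
        sets <- sets[lengths(sets) > 0L]
        if (!length(sets))
            stop("zero surviving sets after restricting to the vocabulary")
    }
    new("GeneSetCollection", sets = sets, provenance = as.character(path))
}

#' Write gene sets to a GMT file
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param path output file path.
#' @param description description field written for every set.
#' @return invisibly, \code{path}.
#' @export
writeGMT <- function(x, path, description = "na") {
    stopifnot(is(x, "GeneSetCollection"))
    lines <- vapply(names(x@sets), function(nm) {
        paste(c(nm, description, x@sets[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Build the binary gene-by-token mask from gene sets
#'
#' Constructs the membership matrix M (genes x sets) with \code{M[i, j] = 1}
#' iff gene i belongs to set j. Sets larger than \code{maxSetSize} member
#' genes (after restriction to the vocabulary) are dropped by default, or
#' truncated to their first \code{maxSetSize} members with
#' \code{oversize = "truncate"}. At most \code{maxSets} sets are retained,
#' keeping the largest (ties broken by name order). Genes belonging to no
#' retained set keep an all-zero row, so reference/query gene alignment is
#' independent of the mask; their expression cannot reach any token.
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param vocabulary character vector of gene identifiers defining row order.
#' @param maxSetSize maximum member genes per retained set (default 300).
#' @param maxSets maximum number of retained sets (default 300).
#' @param oversize \code{"drop"} (default) or \code{"truncate"}.
#' @return a \linkS4class{MaskMatrix}.
#' @examples
#' gsc <- new("GeneSetCollection",
#'     sets = list(S1 = c("A", "B"), S2 = c("B", "C")), provenance = "toy")
#' buildMask(gsc, c("A", "B", "C"))
#' @export
buildMask <- function(collection, vocabulary, maxSetSize = 300L,
                      maxSets = 300L, oversize = c("drop", "truncate")) {
    stopifnot(is(collection, "GeneSetCollection"))
    oversize <- match.arg(oversize)
    vocabulary <- as.character(vocabulary)
    .checkVocabulary(vocabulary)
    voc <- tolower(vocabulary)
    sets <- lapply(collection@sets, function(g) {
        idx <- match(tolower(g), voc)
        sort(unique(idx[!is.na(idx)]))
    })
    sets <- sets[lengths(sets) > 0L]
    if (oversize == "drop") {
        sets <- sets[lengths(sets) <= maxSetSize]
    } else {
        sets <- lapply(sets, function(i) i[seq_len(min(length(i),
            maxSetSize))])
    }
    if (!length(sets))
        stop("zero gene sets survive the size filters")
    if (length(sets) > maxSets) {
        ord <- order(-lengths(sets), names(sets))
        sets <- sets[sort(ord[seq_len(maxSets)])]
    }
    n <- length(vocabulary)
    k <- length(sets)
    ii <- unlist(sets, use.names = FALSE)
    jj <- rep.int(seq_len(k), lengths(sets))
    m <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, k),
        dimnames = list(vocabulary, names(sets)))
    new("MaskMatrix", mask = m, provenance = collection@provenance,
        params = list(maxSetSize = maxSetSize, maxSets = maxSets,
            oversize = oversize))
}

#' Build a random mask
#'
#' Emulates the no-prior-knowledge setting: each of \code{k} tokens draws
#' \code{ceiling(density * n)} member genes uniformly without replacement.
#' Mirrors the random masks with a small fraction (e.g. 1\% or 5\%) of
#' reserved gene-token connections used to show the model is not limited by
#' expert knowledge.
#'
#' @param vocabulary character vector of gene identifiers.
#' @param k number of tokens.
#' @param density fraction of genes per token, in (0, 1].
#' @param seed integer seed; the same seed reproduces the same mask.
#' @return a \linkS4class{MaskMatrix}.
#' @export
randomMask <- function(vocabulary, k, density, seed = 1L) {
    vocabulary <- as.character(vocabulary)
    .checkVocabulary(vocabulary)
    n <- length(vocabulary)
    if (k < 1L) stop("k must be at least 1")
    if (!is.numeric(density) || density <= 0 || density > 1)
        stop("density must lie in (0, 1]")
    sz <- ceiling(density * n)
    ii <- .withSeed(seed, unlist(lapply(seq_len(k), function(j)
        sort(sample.int(n, sz))), use.names = FALSE))
    m <- Matrix::sparseMatrix(i = ii, j = rep(seq_len(k), each = sz), x = 1,
        dims = c(n, k),
        dimnames = list(vocabulary, sprintf("RND%03d", seq_len(k))))
    new("MaskMatrix", mask = m, provenance = "random",
        params = list(k = k, density = density, seed = seed))
}

.checkVocabulary <- function(vocabulary) {
    if (!length(vocabulary))
        stop("gene vocabulary is empty")
    if (anyDuplicated(tolower(vocabulary)))
        stop("duplicate gene identifiers in vocabulary (case-insensitive): ",
            paste(head(unique(vocabulary[duplicated(tolower(vocabulary))]),
                5), collapse = ", "))
    invisible(TRUE)
}

#' Export / import a mask as tab-separated text
#'
#' Writes the dense 0/1 matrix with gene-name row index and set-name header,
#' plus a sidecar \code{<path>.params} file recording the build parameters.
#'
#' @param x a \linkS4class{MaskMatrix}.
#' @param path output TSV path.
#' @return invisibly, \code{path} (for export); a
#'   \linkS4class{MaskMatrix} (for import).
#' @export
exportMask <- function(x, path) {
    stopifnot(is(x, "MaskMatrix"))
    dt <- data.table::as.data.table(as.matrix(x@mask), keep.rownames = "gene")
    data.table::fwrite(dt, path, sep = "\t")
    params <- c(sprintf("provenance\t%s", x@provenance),
        sprintf("%s\t%s", names(x@params), unlist(x@params)))
    writeLines(params, paste0(path, ".params"))
    invisible(path)
}

#' @rdname exportMask
#' @export
importMask <- function(path) {
    df <- as.data.frame(data.table::fread(path, sep = "\t"))
    genes <- df[[1L]]
    m <- Matrix::Matrix(as.matrix(df[, -1L, drop = FALSE]),
        sparse = TRUE)
    rownames(m) <- genes
    prov <- "imported"
    pf <- paste0(path, ".params")
    if (file.exists(pf)) {
        pl <- strsplit(readLines(pf), "\t")
        kv <- vapply(pl, `[`, character(1), 2)
        names(kv) <- vapply(pl, `[`, character(1), 1)
        if (!is.na(kv["provenance"])) prov <- unname(kv["provenance"])
    }
    new("MaskMatrix", mask = m, provenance = prov, params = list())
}

#' @describeIn geneNames genes (rows) of the mask.
#' @export
setMethod("geneNames", "MaskMatrix", function(x) rownames(x@mask))

#' @describeIn tokenNames retained gene sets (columns) of the mask.
#' @export
setMethod("tokenNames", "MaskMatrix", function(x) colnames(x@mask))

#' @describeIn geneSets the stored list of sets.
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' Binary mask values
#'
#' @param x a \linkS4class{MaskMatrix}.
#' @return the genes x sets sparse membership matrix.
#' @export
maskValues <- function(x) {
    stopifnot(is(x, "MaskMatrix"))
    x@mask
}

setMethod("show", "GeneSetCollection", function(object) {
    sz <- lengths(object@sets)
    cat("GeneSetCollection with", length(sz), "sets",
        sprintf("(sizes %d-%d, median %.0f)\n", min(sz), max(sz),
            stats::median(sz)))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "MaskMatrix", function(object) {
    m <- object@mask
    cat(sprintf("MaskMatrix: %d genes x %d gene sets, %d connections\n",
        nrow(m), ncol(m), as.integer(sum(m))))
    cat("  provenance:", object@provenance, "\n")
})
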
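#' Model architecture configuration
#'
#' Defaults: embedding dimension \code{m = 48} (each gene-set token is a
#' 48-dimensional learned vector, i.e. the masked linear embedding is
#' repeated 48 times in parallel), \code{H = 4} attention heads of
#' dimension \code{m/H} each, a single attention block, a two-layer
#' feed-forward of width \code{2m} after the attention sublayer, and a
#' classifier with one hidden layer of width \code{2m}. Residual
#' connections wrap both sublayers; layer normalization (non-affine) is
#' applied pre-sublayer. The per-head attention logits are scaled by
#' \code{1/sqrt(m/H)}.
#'
#' @param m embedding dimension (default 48); must be divisible by H.
#' @param H number of attention heads (default 4).
#' @param depth number of attention blocks (default 1).
#' @param ffnHidden feed-forward hidden width (default \code{2 * m}).
#' @param classifierHidden classifier hidden width (default \code{2 * m}).
#' @param dropout dropout fraction applied during training to the attention
#'   output and feed-forward hidden activations (default 0).
#' @param unknownCutoff probability threshold for Unknown calling
#'   (default 0.95).
#' @param seed integer seed for weight initialization.
#' @return a named list.
#' @export
modelConfig <- function(m = 48L, H = 4L, depth = 1L, ffnHidden = 2L * m,
                        classifierHidden = 2L * m, dropout = 0,
                        unknownCutoff = 0.95, seed = 1L) {
    m <- as.integer(m); H <- as.integer(H); depth <- as.integer(depth)
    if (m %% H != 0L) stop("H must divide m")
    if (depth < 1L) stop("depth must be at least 1")
    if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
    if (unknownCutoff <= 0 || unknownCutoff > 1)
        stop("unknownCutoff must lie in (0, 1]")
    list(m = m, H = H, depth = depth, ffnHidden = as.integer(ffnHidden),
        classifierHidden = as.integer(classifierHidden), dropout = dropout,
        unknownCutoff = unknownCutoff, seed = as.integer(seed))
}

# Dense 0/1 matrix replicating the mask m times column-wise: column
# (d-1)*k + j corresponds to token j, embedding dimension d.
.maskFlat <- function(mask, m) {
    M <- as.matrix(maskValues(mask))
    M[, rep(seq_len(ncol(M)), m), drop = FALSE]
}

# Initialize all learnable arrays. Uniform fan-in scaling on the unmasked
# embedding entries (fan-in of token j = its set size); class token is a
# small Gaussian. Everything is drawn under config$seed.
.initParams <- function(mask, nClasses, cfg) {
    M <- maskValues(mask)
    n <- nrow(M); k <- ncol(M)
    m <- cfg$m; f <- cfg$ffnHidden; hh <- cfg$classifierHidden
    mf <- .maskFlat(mask, m)
    onIdx <- which(mf != 0)
    setSize <- Matrix::colSums(M)
    colOfIdx <- ((onIdx - 1L) %/% n) + 1L         # column in the flat layout
    tokOfIdx <- ((colOfIdx - 1L) %% k) + 1L       # token of that column
    .u <- function(nr, nc2, fanin)
        matrix(stats::runif(nr * nc2, -1, 1) / sqrt(fanin), nr, nc2)
    .withSeed(cfg$seed, {
        # non-negative fan-in-scaled init: every token starts out as a
        # (randomly re-weighted) gene-set activity score, which is the
        # feature the classifier ultimately needs, instead of a
        # random-sign sum whose 25+ signs SGD would first have to align
        Wemb <- matrix(0, n, k * m)
        Wemb[onIdx] <- stats::runif(length(onIdx), 0, 2) /
            sqrt(setSize[tokOfIdx])
        blocks <- lapply(seq_len(cfg$depth), function(b) list(
            Wq = .u(m, m, m), Wk = .u(m, m, m), Wv = .u(m, m, m),
            Wo = .u(m, m, m),
            W1 = .u(m, f, m), b1 = numeric(f),
            W2 = .u(f, m, f), b2 = numeric(m)))
        list(Wemb = Wemb, cls = stats::rnorm(m, 0, 0.02), blocks = blocks,
            Wc1 = .u(m, hh, m), bc1 = numeric(hh),
            Wc2 = .u(hh, nClasses, hh), bc2 = numeric(nClasses))
    })
}

# Forward pass for one cell. `tflat` is the cell's row of E %*% Wemb
# (length k*m, token index varying fastest). Returns class probabilities,
# the final block's head-averaged CLS-to-token attention, and (optionally)
# the caches needed for backprop. Dropout masks are drawn by the caller's
# RNG stream when train = TRUE.
.forwardOne <- function(params, cfg, tflat, k, collect = FALSE,
                        train = FALSE) {
    m <- cfg$m; H <- cfg$H; dh <- m %/% H
    scale <- 1 / sqrt(dh)
    p <- cfg$dropout
    X <- rbind(params$cls, matrix(tflat, k, m))
    caches <- if (collect) vector("list", cfg$depth)
    clsAttn <- NULL
    # post-norm residual blocks (as in the original attention
    # architecture): layer norm is applied after each residual add, so the
    # first attention sees raw token magnitudes — the gene-set activity
    # level a token encodes — rather than per-token-normalized patterns
    for (b in seq_len(cfg$depth)) {
        blk <- params$blocks[[b]]
        Q <- X %*% blk$Wq; K <- X %*% blk$Wk; V <- X %*% blk$Wv
        Hc <- matrix(0, 1L + k, m)
        Alist <- vector("list", H)
        for (h in seq_len(H)) {
            idx <- ((h - 1L) * dh + 1L):(h * dh)
            A <- .softmaxRows(tcrossprod(Q[, idx], K[, idx]) * scale)
            Alist[[h]] <- A
            Hc[, idx] <- A %*% V[, idx]
        }
        O <- Hc %*% blk$Wo
        dmO <- NULL
        if (train && p > 0) {
            dmO <- matrix((stats::runif(length(O)) >= p) / (1 - p),
                nrow(O), ncol(O))
            O <- O * dmO
        }
        l1 <- .lnForward(X + O)
        X1 <- l1$y
        F1pre <- sweep(X1 %*% blk$W1, 2L, blk$b1, "+")
        F1 <- .gelu(F1pre)
        dmF <- NULL
        if (train && p > 0) {
            dmF <- matrix((stats::runif(length(F1)) >= p) / (1 - p),
                nrow(F1), ncol(F1))
            F1 <- F1 * dmF
        }
        l2 <- .lnForward(X1 + sweep(F1 %*% blk$W2, 2L, blk$b2, "+"))
        X2 <- l2$y
        if (any(!is.finite(X2)))
            stop("non-finite activations in attention block ", b)
        clsAttn <- Reduce(`+`, lapply(Alist, function(A)
            A[1L, -1L]))/H
        if (collect)
            caches[[b]] <- list(X = X, Q = Q, K = K, V = V,
                Alist = Alist, Hc = Hc, dmO = dmO, inv1 = l1$inv,
                X1 = X1, F1pre = F1pre, F1 = F1, dmF = dmF,
                inv2 = l2$inv, X2 = X2)
        X <- X2
    }
    clsRow <- X[1L, , drop = FALSE]
    c1pre <- clsRow %*% params$Wc1 + rep(params$bc1, each = 1L)
    c1 <- .gelu(c1pre)
    logits <- c1 %*% params$Wc2 + rep(params$bc2, each = 1L)
    probs <- drop(.softmaxRows(logits))
    list(probs = probs, attn = clsAttn,
        cache = if (collect) list(blocks = caches, clsRow = clsRow,
            c1pre = c1pre, c1 = c1))
}

# Backprop for one cell. `dlogits` is (probs - onehot) * weight, a length-nc
# vector. Accumulates parameter gradients into the environment `ge` and
# returns the gradient w.r.t. the cell's flat token vector.
.backwardOne <- function(params, cfg, cache, dlogits, k) {
    m <- cfg$m; H <- cfg$H; dh <- m %/% H
    scale <- 1 / sqrt(dh)
    g <- list()
    dlogits <- matrix(dlogits, 1L)
    g$Wc2 <- crossprod(cache$c1, dlogits)
    g$bc2 <- drop(dlogits)
    dc1pre <- (dlogits %*% t(params$Wc2)) * .geluGrad(cache$c1pre)
    g$Wc1 <- crossprod(cache$clsRow, dc1pre)
    g$bc1 <- drop(dc1pre)
    dX <- matrix(0, 1L + k, m)
    dX[1L, ] <- dc1pre %*% t(params$Wc1)
    g$blocks <- vector("list", cfg$depth)
    for (b in rev(seq_len(cfg$depth))) {
        blk <- params$blocks[[b]]
        cc <- cache$blocks[[b]]
        gb <- list()
        # second (feed-forward) residual + post-norm
        dZ2 <- .lnBackward(dX, cc$X2, cc$inv2)
        dX1 <- dZ2
        dF2 <- dZ2
        gb$W2 <- crossprod(cc$F1, dF2)
        gb$b2 <- colSums(dF2)
        dF1 <- dF2 %*% t(blk$W2)
        if (!is.null(cc$dmF)) dF1 <- dF1 * cc$dmF
        dF1pre <- dF1 * .geluGrad(cc$F1pre)
        gb$W1 <- crossprod(cc$X1, dF1pre)
        gb$b1 <- colSums(dF1pre)
        dX1 <- dX1 + dF1pre %*% t(blk$W1)
        # first (attention) residual + post-norm
        dZ1 <- .lnBackward(dX1, cc$X1, cc$inv1)
        dO <- dZ1
        if (!is.null(cc$dmO)) dO <- dO * cc$dmO
        gb$Wo <- crossprod(cc$Hc, dO)
        dHc <- dO %*% t(blk$Wo)
        dQ <- matrix(0, 1L + k, m); dK <- dQ; dV <- dQ
        for (h in seq_len(H)) {
            idx <- ((h - 1L) * dh + 1L):(h * dh)
            A <- cc$Alist[[h]]
            dhead <- dHc[, idx, drop = FALSE]
            dA <- tcrossprod(dhead, cc$V[, idx, drop = FALSE])
            dV[, idx] <- crossprod(A, dhead)
            dS <- A * (dA - rowSums(dA * A))
            dQ[, idx] <- (dS %*% cc$K[, idx, drop = FALSE]) * scale
            dK[, idx] <- crossprod(dS, cc$Q[, idx, drop = FALSE]) * scale
        }
        gb$Wq <- crossprod(cc$X, dQ)
        gb$Wk <- crossprod(cc$X, dK)
        gb$Wv <- crossprod(cc$X, dV)
        dX <- dZ1 + dQ %*% t(blk$Wq) + dK %*% t(blk$Wk) +
            dV %*% t(blk$Wv)
        g$blocks[[b]] <- gb
    }
    g$cls <- dX[1L, ]
    list(grads = g, dtflat = as.vector(dX[-1L, , drop = FALSE]))
}

# Forward a cells x genes matrix (already normalized + aligned) through the
# model. Returns probabilities (cells x nc) and the attention embedding
# (cells x k).
.forwardMatrix <- function(params, cfg, X, k, labels) {
    Tflat <- X %*% params$Wemb
    nc <- length(labels)
    probs <- matrix(0, nrow(X), nc,
        dimnames = list(rownames(X), labels))
    attn <- matrix(0, nrow(X), k)
    for (i in seq_len(nrow(X))) {
        fw <- .forwardOne(params, cfg, Tflat[i, ], k)
        probs[i, ] <- fw$probs
        attn[i, ] <- fw$attn
    }
    list(probs = probs, attn = attn)
}

#' Run the model forward on expression data
#'
#' Applies the full inference pipeline — normalization (as configured at
#' training time), gene alignment, masked embedding, attention blocks,
#' classifier — and returns both the class probability matrix and the
#' class-token attention scores. Deterministic: dropout is disabled at
#' evaluation.
#'
#' @param model a \linkS4class{TokenTransformer}.
#' @param x a \code{SingleCellExperiment} or cells-by-genes matrix.
#' @param chunkSize cells processed per chunk (results are independent of
#'   chunking).
#' @return list with \code{probabilities} (cells x classes) and
#'   \code{attention} (cells x tokens) matrices.
#' @export
modelForward <- function(model, x, chunkSize = 1024L) {
    stopifnot(is(model, "TokenTransformer"))
    cfg <- model@config
    X <- .modelInput(x, geneNames(model),
        normalize = isTRUE(cfg$normalize),
        sizeFactor = if (is.null(cfg$sizeFactor)) 1e4 else cfg$sizeFactor)
    k <- ncol(maskValues(model@mask))
    nCells <- nrow(X)
    probs <- matrix(0, nCells, length(model@labels),
        dimnames = list(rownames(X), model@labels))
    attn <- matrix(0, nCells, k,
        dimnames = list(rownames(X), tokenNames(model@mask)))
    start <- 1L
    while (start <= nCells) {
        end <- min(start + chunkSize - 1L, nCells)
        fw <- .forwardMatrix(model@params, cfg,
            X[start:end, , drop = FALSE], k, model@labels)
        probs[start:end, ] <- fw$probs
        attn[start:end, ] <- fw$attn
        start <- end + 1L
    }
    list(probabilities = probs, attention = attn)
}

#' @describeIn geneNames genes of the model's vocabulary.
#' @export
setMethod("geneNames", "TokenTransformer",
    function(x) rownames(maskValues(x@mask)))

#' @describeIn tokenNames tokens of the model.
#' @export
setMethod("tokenNames", "TokenTransformer",
    function(x) colnames(maskValues(x@mask)))

#' @describeIn classLabels training classes of the model.
#' @export
setMethod("classLabels", "TokenTransformer", function(x) x@labels)

#' @describeIn trainingHistory per-epoch metrics recorded by [trainModel()].
#' @export
setMethod("trainingHistory", "TokenTransformer", function(x) x@history)

setMethod("show", "TokenTransformer", function(object) {
    M <- maskValues(object@mask)
    cfg <- object@config
    cat(sprintf(paste0("TokenTransformer: %d genes -> %d tokens ",
        "(m = %d, H = %d, depth = %d)\n"), nrow(M), ncol(M), cfg$m,
        cfg$H, cfg$depth))
    cat(sprintf("  classes (%d): %s\n", length(object@labels),
        paste(head(object@labels, 6), collapse = ", ")))
    if (nrow(object@history))
        cat(sprintf("  trained %d epochs; best validation accuracy %.3f\n",
            nrow(object@history), max(object@history$val_acc)))
})

#' Save / load a model checkpoint
#'
#' Serializes the full model (parameters, mask, vocabularies, config,
#' history) so that loading restores bit-identical forward behavior.
#'
#' @param model a \linkS4class{TokenTransformer}.
#' @param path checkpoint file path.
#' @return \code{loadModel} returns the restored model.
#' @export
saveModel <- function(model, path) {
    stopifnot(is(model, "TokenTransformer"))
    saveRDS(model, path)
    invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
    model <- readRDS(path)
    if (!is(model, "TokenTransformer"))
        stop("not a TokenTransformer checkpoint: ", path)
    model
}
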
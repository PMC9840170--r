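#' Training configuration
#'
#' Defaults: 20 epochs of SGD with momentum 0.9, batch size 256, initial
#' learning rate 0.3 decayed along a cosine schedule, weight decay 1e-4.
#' 30\% of the reference is held out as a label-stratified validation set
#' and the epoch with the best validation accuracy is returned.
#'
#' @param epochs number of epochs (default 20).
#' @param batchSize minibatch size (default 256).
#' @param lr0 initial learning rate (default 0.3).
#' @param momentum SGD momentum (default 0.9).
#' @param weightDecay L2 penalty on weight matrices (default 1e-4; biases
#'   and the class token are exempt).
#' @param valFraction validation fraction (default 0.30).
#' @param classWeights when TRUE, weight the cross-entropy by inverse class
#'   frequency (default FALSE: no reweighting).
#' @param seed integer seed controlling the split, shuffling and dropout.
#' @return a named list.
#' @export
trainConfig <- function(epochs = 20L, batchSize = 256L, lr0 = 0.3,
                        momentum = 0.9, weightDecay = 1e-4,
                        valFraction = 0.30, classWeights = FALSE,
                        seed = 1L) {
    if (epochs < 1L) stop("epochs must be at least 1")
    if (batchSize < 1L) stop("batchSize must be at least 1")
    if (valFraction <= 0 || valFraction >= 1)
        stop("valFraction must lie in (0, 1)")
    list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
        lr0 = lr0, momentum = momentum, weightDecay = weightDecay,
        valFraction = valFraction, classWeights = isTRUE(classWeights),
        seed = as.integer(seed))
}

#' Cosine learning-rate schedule
#'
#' \code{lr = lr0 * (1 + cos(pi * epoch / epochs)) / 2} for 0-based
#' \code{epoch}; starts at \code{lr0} and decays smoothly towards 0,
#' avoiding large steps late in training.
#'
#' @param epoch 0-based epoch index.
#' @param epochs total number of epochs.
#' @param lr0 initial learning rate.
#' @return the learning rate for that epoch.
#' @export
cosineLR <- function(epoch, epochs, lr0) {
    stopifnot(all(epoch >= 0), all(epoch < epochs))
    lr0 * (1 + cos(pi * epoch / epochs)) / 2
}

# Label-stratified split indices: each class contributes round(fraction * n)
# cells (at least 1 when the class has >= 2 cells, never all of them) to
# validation. Singleton classes stay in training with a warning.
.stratifiedSplit <- function(labels, fraction, seed) {
    .withSeed(seed, {
        val <- integer(0)
        for (cl in unique(labels)) {
            idx <- which(labels == cl)
            n <- length(idx)
            if (n < 2L) {
                warning("class '", cl,
                    "' has a single cell; kept in training")
                next
            }
            nv <- min(max(round(fraction * n), 1L), n - 1L)
            val <- c(val, sample(idx, nv))
        }
        list(train = setdiff(seq_along(labels), val), val = sort(val))
    })
}

#' Stratified train/validation split
#'
#' @param x a \code{SingleCellExperiment} with labels in
#'   \code{colData(x)$label} (or the column named by \code{labelKey}).
#' @param fraction validation fraction (default 0.30).
#' @param seed integer seed; the same seed reproduces the same split.
#' @param labelKey colData column holding the labels.
#' @return list with elements \code{train} and \code{val}, both
#'   \code{SingleCellExperiment}s; disjoint and exhaustive.
#' @export
splitTrainVal <- function(x, fraction = 0.30, seed = 1L,
                          labelKey = "label") {
    labels <- SummarizedExperiment::colData(x)[[labelKey]]
    if (is.null(labels)) stop("no '", labelKey, "' column in colData")
    sp <- .stratifiedSplit(as.character(labels), fraction, seed)
    list(train = x[, sp$train], val = x[, sp$val])
}

#' Train a pathway-token attention model
#'
#' Supervised training of the masked-embedding transformer on a labeled
#' reference. The loss is the mean cross-entropy between the softmax class
#' probabilities and the one-hot labels; the optimizer is SGD with momentum
#' under a cosine learning-rate decay. The binary mask is re-applied to the
#' embedding weights after every optimizer step, so off-mask weights are
#' exactly zero at all times. The returned model carries the parameters of
#' the epoch with the best validation accuracy (ties resolved to the
#' earlier epoch).
#'
#' @param ref a \code{SingleCellExperiment} with a \code{"counts"} assay and
#'   cell-type labels in \code{colData}.
#' @param mask a \linkS4class{MaskMatrix}; its gene vocabulary defines the
#'   model input space.
#' @param labelKey colData column holding the labels (default
#'   \code{"label"}).
#' @param config architecture configuration from [modelConfig()].
#' @param training optimization configuration from [trainConfig()].
#' @param normalize library-size normalize + log1p the input (default TRUE);
#'   set FALSE to feed raw counts.
#' @param sizeFactor per-cell total used when normalizing (default 1e4).
#' @param verbose print per-epoch metrics.
#' @return a trained \linkS4class{TokenTransformer}; see
#'   [trainingHistory()] for per-epoch metrics.
#' @export
trainModel <- function(ref, mask, labelKey = "label",
                       config = modelConfig(), training = trainConfig(),
                       normalize = TRUE, sizeFactor = 1e4,
                       verbose = FALSE) {
    stopifnot(is(mask, "MaskMatrix"))
    labels <- SummarizedExperiment::colData(ref)[[labelKey]]
    if (is.null(labels)) stop("no '", labelKey, "' column in colData")
    labels <- as.character(labels)
    classes <- sort(unique(labels))
    if (length(classes) < 2L)
        stop("training requires at least 2 cell-type classes")
    if ("Unknown" %in% classes)
        stop("'Unknown' is a reserved label and cannot appear in training")
    X <- .modelInput(ref, geneNames(mask), normalize = normalize,
        sizeFactor = sizeFactor)
    y <- match(labels, classes)
    nc <- length(classes)
    k <- ncol(maskValues(mask))
    cfg <- config
    cfg$normalize <- normalize
    cfg$sizeFactor <- sizeFactor
    params <- .initParams(mask, nc, cfg)
    mf <- .maskFlat(mask, cfg$m)
    cw <- if (training$classWeights) {
        tab <- tabulate(y, nc)
        w <- length(y) / (nc * tab)
        w / mean(w[y])
    } else rep(1, nc)

    sp <- .stratifiedSplit(labels, training$valFraction, training$seed)
    itr <- sp$train; iva <- sp$val
    momentumBuf <- rapply(params, function(p) p * 0, how = "replace")
    history <- data.frame(epoch = integer(), lr = numeric(),
        train_loss = numeric(), train_acc = numeric(),
        val_loss = numeric(), val_acc = numeric())
    best <- list(acc = -Inf, params = NULL)

    evalSplit <- function(idx) {
        if (!length(idx)) return(c(NA_real_, NA_real_))
        fw <- .forwardMatrix(params, cfg, X[idx, , drop = FALSE], k,
            classes)
        pt <- fw$probs[cbind(seq_along(idx), y[idx])]
        c(mean(-log(pmax(pt, 1e-12)) * cw[y[idx]]),
            mean(max.col(fw$probs, ties.method = "first") == y[idx]))
    }

    .withSeed(training$seed + 1L, for (epoch in seq_len(training$epochs)) {
        lr <- cosineLR(epoch - 1L, training$epochs, training$lr0)
        ord <- sample(itr)
        nTrain <- length(ord)
        epochLoss <- 0; epochHits <- 0
        nBatches <- ceiling(nTrain / training$batchSize)
        for (bi in seq_len(nBatches)) {
            bidx <- ord[((bi - 1L) * training$batchSize + 1L):
                min(bi * training$batchSize, nTrain)]
            B <- length(bidx)
            E <- X[bidx, , drop = FALSE]
            Tflat <- E %*% params$Wemb
            grads <- rapply(params, function(p) p * 0, how = "replace")
            dTflat <- matrix(0, B, ncol(Tflat))
            for (ci in seq_len(B)) {
                yi <- y[bidx[ci]]
                fw <- .forwardOne(params, cfg, Tflat[ci, ], k,
                    collect = TRUE, train = TRUE)
                pt <- max(fw$probs[yi], 1e-12)
                epochLoss <- epochLoss + cw[yi] * -log(pt)
                epochHits <- epochHits +
                    (which.max(fw$probs) == yi)
                dlog <- fw$probs
                dlog[yi] <- dlog[yi] - 1
                bw <- .backwardOne(params, cfg, fw$cache,
                    dlog * (cw[yi] / B), k)
                dTflat[ci, ] <- bw$dtflat
                g <- bw$grads
                grads$cls <- grads$cls + g$cls
                grads$Wc1 <- grads$Wc1 + g$Wc1
                grads$bc1 <- grads$bc1 + g$bc1
                grads$Wc2 <- grads$Wc2 + g$Wc2
                grads$bc2 <- grads$bc2 + g$bc2
                for (b in seq_len(cfg$depth))
                    for (nm in names(g$blocks[[b]]))
                        grads$blocks[[b]][[nm]] <-
                            grads$blocks[[b]][[nm]] + g$blocks[[b]][[nm]]
            }
            grads$Wemb <- crossprod(E, dTflat) * mf
            upd <- .sgdStep(params, grads, momentumBuf, lr,
                training$momentum, training$weightDecay)
            params <- upd$params
            params$Wemb <- params$Wemb * mf
            momentumBuf <- upd$buf
            if (!is.finite(epochLoss))
                stop(sprintf("non-finite loss at epoch %d, batch %d",
                    epoch, bi))
        }
        trainLoss <- epochLoss / nTrain
        trainAcc <- epochHits / nTrain
        vm <- evalSplit(iva)
        if (!length(iva)) vm <- c(trainLoss, trainAcc)
        history[epoch, ] <- list(epoch, lr, trainLoss, trainAcc,
            vm[1], vm[2])
        if (vm[2] > best$acc) best <- list(acc = vm[2], params = params)
        if (verbose)
            message(sprintf(
                "epoch %2d  lr %.4g  train loss %.4f acc %.3f  val loss %.4f acc %.3f",
                epoch, lr, trainLoss, trainAcc, vm[1], vm[2]))
    })
    new("TokenTransformer", mask = mask, params = best$params,
        labels = classes, config = cfg, history = history)
}

# One SGD-with-momentum step over the nested parameter list. Weight decay
# applies to 2-d weight matrices only.
.sgdStep <- function(params, grads, buf, lr, momentum, wd) {
    step <- function(p, g, v, decay) {
        v <- momentum * v + g + (if (decay) wd * p else 0)
        list(p = p - lr * v, v = v)
    }
    walk <- function(p, g, v) {
        for (nm in names(p)) {
            if (is.list(p[[nm]])) {
                r <- walk(p[[nm]], g[[nm]], v[[nm]])
                p[[nm]] <- r$p; v[[nm]] <- r$v
            } else {
                s <- step(p[[nm]], g[[nm]], v[[nm]],
                    decay = is.matrix(p[[nm]]))
                p[[nm]] <- s$p; v[[nm]] <- s$v
            }
        }
        list(p = p, v = v)
    }
    r <- walk(params, grads, buf)
    list(params = r$p, buf = r$v)
}
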
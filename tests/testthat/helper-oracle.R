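# Straight-line reference implementation of the forward pass (masked
# embedding -> class-token augmentation -> multi-head self-attention with
# post-norm residual blocks -> classifier), written with explicit loops and
# kept independent of the package internals it checks.
oracleForward <- function(params, mask, cfg, e) {
    M <- as.matrix(maskValues(mask))
    n <- nrow(M); k <- ncol(M)
    m <- cfg$m; H <- cfg$H; dh <- m / H
    softmax <- function(z) { z <- z - max(z); exp(z) / sum(exp(z)) }
    ln <- function(x) t(apply(x, 1, function(r) {
        (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)
    }))
    gelu <- function(x) x * pnorm(x)
    Tmat <- matrix(0, k, m)
    for (j in seq_len(k)) for (d in seq_len(m)) {
        s <- 0
        for (i in seq_len(n))
            s <- s + M[i, j] * params$Wemb[i, (d - 1) * k + j] * e[i]
        Tmat[j, d] <- s
    }
    X <- rbind(params$cls, Tmat)
    attn <- NULL
    Alist <- NULL
    for (b in seq_len(cfg$depth)) {
        blk <- params$blocks[[b]]
        Q <- X %*% blk$Wq; K <- X %*% blk$Wk; V <- X %*% blk$Wv
        heads <- NULL
        Alist <- vector("list", H)
        for (h in seq_len(H)) {
            idx <- ((h - 1) * dh + 1):(h * dh)
            S <- matrix(0, 1 + k, 1 + k)
            for (r in seq_len(1 + k)) for (cc in seq_len(1 + k))
                S[r, cc] <- sum(Q[r, idx] * K[cc, idx]) / sqrt(dh)
            A <- t(apply(S, 1, softmax))
            Alist[[h]] <- A
            heads <- cbind(heads, A %*% V[, idx, drop = FALSE])
        }
        O <- heads %*% blk$Wo
        X1 <- ln(X + O)
        F1 <- gelu(sweep(X1 %*% blk$W1, 2, blk$b1, "+"))
        X <- ln(X1 + sweep(F1 %*% blk$W2, 2, blk$b2, "+"))
        attn <- Reduce(`+`, lapply(Alist, function(A) A[1, -1])) / H
    }
    c1 <- gelu(X[1, ] %*% params$Wc1 + params$bc1)
    probs <- softmax(drop(c1 %*% params$Wc2 + params$bc2))
    list(probs = probs, attn = attn, A = Alist, tokens = Tmat)
}
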
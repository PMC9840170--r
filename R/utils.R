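# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards so package functions never perturb
# user-level reproducibility.
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
            inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Row-wise softmax of a matrix, numerically stabilized.
.softmaxRows <- function(x) {
    x <- x - apply(x, 1L, max)
    e <- exp(x)
    e / rowSums(e)
}

.gelu <- function(x) x * stats::pnorm(x)

.geluGrad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Non-affine layer normalization over rows; returns normalized matrix with
# the inverse sd kept for backprop.
.lnForward <- function(x, eps = 1e-5) {
    mu <- rowMeans(x)
    xc <- x - mu
    inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
    list(y = xc * inv, inv = inv)
}

.lnBackward <- function(dy, y, inv) {
    (dy - rowMeans(dy) - y * rowMeans(dy * y)) * inv
}
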
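test_that("masked embedding sums member-gene expression per token and dimension", {
    ti <- tinyInstance()
    e <- c(0.5, 1.2, 0, 2.1, 3.3, 0.7)
    tflat <- drop(e %*% ti$params$Wemb)
    tokens <- matrix(tflat, 3, 4)
    orc <- oracleForward(ti$params, ti$mask, ti$cfg, e)
    expect_equal(tokens, orc$tokens, tolerance = 1e-12)

    # all-ones weights over an all-ones mask: every token entry = sum(e)
    gsc <- new("GeneSetCollection",
        sets = list(S1 = c("a", "b", "c"), S2 = c("a", "b", "c")),
        provenance = "toy")
    mk <- buildMask(gsc, c("a", "b", "c"))
    mf <- pathattn:::.maskFlat(mk, 4L)
    tokens2 <- matrix(drop(c(1, 2, 3) %*% mf), 2, 4)
    expect_true(all(tokens2 == 6))
})

test_that("tokens are annihilated by the mask: non-member genes cannot reach them", {
    ti <- tinyInstance()
    e <- runif(6)
    e2 <- e
    e2[1] <- e[1] + 100   # g1 belongs to S1 only
    t1 <- matrix(drop(e %*% ti$params$Wemb), 3, 4)
    t2 <- matrix(drop(e2 %*% ti$params$Wemb), 3, 4)
    expect_identical(t1[2, ], t2[2, ])  # S2 = {g3, g4} untouched
    expect_identical(t1[3, ], t2[3, ])  # S3 = {g5, g6} untouched
    expect_false(all(t1[1, ] == t2[1, ]))
})

test_that("forward matches the straight-line oracle on the 6-gene instance", {
    ti <- tinyInstance()
    set.seed(5)
    for (r in 1:5) {
        e <- abs(rnorm(6))
        fw <- pathattn:::.forwardMatrix(ti$params, ti$cfg,
            matrix(e, 1, dimnames = list("c", sprintf("g%d", 1:6))), 3L,
            c("A", "B"))
        orc <- oracleForward(ti$params, ti$mask, ti$cfg, e)
        expect_equal(drop(fw$probs), orc$probs, tolerance = 1e-5,
            ignore_attr = TRUE)
        expect_equal(drop(fw$attn), orc$attn, tolerance = 1e-5,
            ignore_attr = TRUE)
        # softmax invariants at 1e-6
        expect_equal(sum(fw$probs), 1, tolerance = 1e-6)
        for (A in orc$A) {
            expect_equal(unname(rowSums(A)), rep(1, 4), tolerance = 1e-6)
            expect_true(all(A >= 0 & A <= 1))
        }
    }
})

test_that("identical token rows receive equal attention from every query", {
    ti <- tinyInstance()
    # expression making S2 and S3 identical rows is hard to craft; instead
    # feed a token matrix with duplicated rows straight into one block
    params <- ti$params
    cfg <- ti$cfg
    tflat <- rep(0, 12)   # all tokens zero => rows 2..4 identical
    fw <- pathattn:::.forwardOne(params, cfg, tflat, 3L, collect = TRUE)
    A <- fw$cache$blocks[[1]]$Alist[[1]]
    # keys of the three zero tokens are identical: equal attention weights
    expect_equal(A[1, 2], A[1, 3], tolerance = 1e-12)
    expect_equal(A[1, 3], A[1, 4], tolerance = 1e-12)
})

test_that("classifier reduces to uniform probabilities with zero weights", {
    ti <- tinyInstance()
    params <- ti$params
    params$Wc1[] <- 0; params$bc1[] <- 0
    params$Wc2[] <- 0; params$bc2[] <- 0
    fw <- pathattn:::.forwardOne(params, ti$cfg, runif(12), 3L)
    expect_equal(unname(fw$probs), c(0.5, 0.5))
    # softmax arithmetic: logits (ln 2, 0) -> (2/3, 1/3)
    expect_equal(drop(pathattn:::.softmaxRows(matrix(c(log(2), 0), 1))),
        c(2 / 3, 1 / 3))
})

test_that("forward is deterministic and permutation-equivariant in gene order", {
    model <- smallModel()
    sim <- smallSim()
    counts <- t(as.matrix(SummarizedExperiment::assay(sim$query,
        "counts")))[1:20, ]
    f1 <- modelForward(model, counts)
    f2 <- modelForward(model, counts)
    expect_identical(f1, f2)
    expect_equal(unname(rowSums(f1$probabilities)), rep(1, 20),
        tolerance = 1e-6)
    expect_true(all(f1$attention >= 0 & f1$attention <= 1))
    expect_true(all(rowSums(f1$attention) <= 1 + 1e-8))
    # permuting gene columns together with their names changes nothing
    perm <- sample(ncol(counts))
    f3 <- modelForward(model, counts[, perm])
    expect_equal(f1$probabilities, f3$probabilities, tolerance = 1e-12)
})

test_that("off-mask embedding weights are exactly zero after training", {
    model <- smallModel()
    mf <- pathattn:::.maskFlat(model@mask, model@config$m)
    expect_identical(unname(model@params$Wemb[mf == 0]),
        rep(0, sum(mf == 0)))
    # and perturbing a gene outside a token's member set leaves that token
    # unchanged to machine precision
    M <- as.matrix(maskValues(model@mask))
    j <- 1L
    outsider <- which(M[, j] == 0)[1]
    e <- runif(nrow(M)); e2 <- e; e2[outsider] <- e2[outsider] + 50
    k <- ncol(M); m <- model@config$m
    cols <- (seq_len(m) - 1L) * k + j
    expect_identical(drop(e %*% model@params$Wemb[, cols]),
        drop(e2 %*% model@params$Wemb[, cols]))
})

test_that("checkpoint round-trip restores forward behavior exactly", {
    model <- smallModel()
    path <- tempfile(fileext = ".rds")
    saveModel(model, path)
    back <- loadModel(path)
    counts <- t(as.matrix(SummarizedExperiment::assay(smallSim()$query,
        "counts")))[1:10, ]
    expect_identical(modelForward(model, counts),
        modelForward(back, counts))
})
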
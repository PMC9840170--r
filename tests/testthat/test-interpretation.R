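test_that("attention preprocessing scales, logs and projects", {
    a <- matrix(c(0.1, 0.3, 0.2, 0.2), 2, byrow = TRUE,
        dimnames = list(c("c1", "c2"), c("t1", "t2")))
    pp <- preprocessAttention(a)
    expect_equal(unname(pp$processed[1, ]), log1p(c(2500, 7500)))
    expect_equal(unname(pp$processed[2, ]), log1p(c(5000, 5000)))
    # PC scores: rank bounded by min(cells, tokens) - 1 after centering
    set.seed(4)
    a2 <- matrix(runif(100), 20, 5)
    pp2 <- preprocessAttention(a2)
    expect_lte(qr(pp2$pcs)$rank, 4)
    # identical cells get identical PC rows
    a3 <- rbind(a2, a2[1, ])
    pp3 <- preprocessAttention(a3)
    expect_equal(pp3$pcs[1, ], pp3$pcs[21, ], tolerance = 1e-10)
    expect_error(preprocessAttention(-a), "non-negative")
})

test_that("rank-sum marker test matches the exact U-distribution oracle", {
    # perfectly separated token: all 10 group values above all 10 rest.
    # two-sided exact p for U = 100 is 2 / choose(20, 10).
    set.seed(1)
    sep <- c(runif(10, 0.6, 0.9), runif(10, 0.1, 0.4))
    # constant per-cell totals, as for (near-)complete attention rows,
    # so the library-size step is a fixed rescaling
    a <- cbind(tokA = sep, tokB = 1 - sep)
    rownames(a) <- sprintf("c%d", 1:20)
    groups <- rep(c("g1", "g2"), each = 10)
    res <- rankAttentions(a, groups)
    r1 <- res[res$group == "g1" & res$token == "tokA", ]
    expect_equal(r1$p_value, 2 / choose(20, 10), tolerance = 1e-12)
    expect_equal(r1$direction, 1L)
    expect_equal(r1$rank, 1)
    # monotone transforms of the token leave its rank test untouched
    a2 <- cbind(tokA = sep^3, tokB = 1 - sep^3)
    rownames(a2) <- rownames(a)
    res2 <- rankAttentions(a2, groups)
    expect_equal(res2$p_value[res2$token == "tokA"],
        res$p_value[res$token == "tokA"], tolerance = 1e-12)
})

test_that("constant tokens are non-discriminating and BH behaves on ties", {
    # constant row sums keep the constant token constant after the
    # library-size step
    set.seed(2)
    b <- runif(24, 0.1, 0.4)
    a <- cbind(tokA = rep(0.3, 24), tokB = b, tokC = 0.5 - b)
    rownames(a) <- sprintf("c%d", 1:24)
    groups <- rep(c("g1", "g2"), each = 12)
    res <- rankAttentions(a, groups)
    expect_true(all(res$p_value[res$token == "tokA"] == 1))
    # BH: equal raw p-values get equal adjusted values; adjusted >= raw,
    # capped at 1; monotone
    p <- c(0.01, 0.01, 0.04, 0.5)
    adj <- p.adjust(p, "BH")
    expect_equal(adj[1], adj[2])
    expect_true(all(res$p_adj >= res$p_value - 1e-15))
    expect_true(all(res$p_adj <= 1))
    expect_error(rankAttentions(a, rep("one", 24)), "at least 2 groups")
})

test_that("sub-clustering separates well-separated blobs and is reproducible", {
    set.seed(9)
    blob1 <- matrix(runif(40 * 4, 0.00, 0.05), 40, 4)
    blob2 <- matrix(runif(40 * 4, 0.00, 0.05), 40, 4)
    blob2[, 1] <- blob2[, 1] + 0.9   # dominant token flips between blobs
    a <- rbind(blob1, blob2)
    rownames(a) <- sprintf("c%d", 1:80)
    cl <- subclusterCells(a, resolution = 0.3, seed = 2)
    expect_equal(length(unique(cl)), 2L)
    expect_equal(length(unique(cl[1:40])), 1L)
    expect_equal(length(unique(cl[41:80])), 1L)
    expect_identical(cl, subclusterCells(a, resolution = 0.3, seed = 2))
    # one homogeneous blob stays one cluster
    cl1 <- subclusterCells(blob1, resolution = 0.3, seed = 2)
    expect_equal(length(unique(cl1)), 1L)
    expect_error(subclusterCells(a[1:5, ]), "at least 10")
})

test_that("gene importance averages |masked weights| and omits off-mask genes", {
    ti <- tinyInstance()
    model <- ti$model
    k <- 3L; m <- 4L
    # plant: g2's weights for token S1 are 10x every other member weight
    W <- model@params$Wemb
    cols <- (seq_len(m) - 1L) * k + 1L
    W[2, cols] <- 10 * max(abs(W[W != 0]))
    model@params$Wemb <- W
    gi <- geneImportance(model, "S1")
    expect_equal(gi$gene[1], "g2")
    expect_setequal(gi$gene, c("g1", "g2", "g3"))   # members of S1 only
    expect_false(any(c("g4", "g5", "g6") %in% gi$gene))
    # constant weights c give importance |c|
    model@params$Wemb[1, cols] <- -0.7
    gi2 <- geneImportance(model, "S1")
    expect_equal(gi2$importance[gi2$gene == "g1"], 0.7)
    # invariant to sign flips
    model2 <- model
    model2@params$Wemb <- -model@params$Wemb
    gi3 <- geneImportance(model2, "S1")
    expect_equal(gi3$importance, gi2$importance)
    expect_error(geneImportance(model, "NOPE"), "unknown token")
})
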
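test_that("loadExpression reads CSV with labels and rejects bad input", {
    csv <- tempfile(fileext = ".csv")
    writeLines(c("cell,A,B,celltype",
        "c1,1,0,alpha", "c2,2,3,beta", "c3,0,5,alpha"), csv)
    x <- loadExpression(csv, labelKey = "celltype")
    expect_equal(dim(x), c(2L, 3L))           # 2 genes, 3 cells
    expect_equal(rownames(x), c("A", "B"))
    expect_equal(x$label, c("alpha", "beta", "alpha"))
    expect_equal(unname(SummarizedExperiment::assay(x, "counts")["B", ]),
        c(0, 3, 5))

    expect_error(loadExpression(csv, labelKey = "nope"), "not found")

    neg <- tempfile(fileext = ".csv")
    writeLines(c("cell,A,B", "c1,1,-2"), neg)
    expect_error(loadExpression(neg), "negative")

    dup <- tempfile(fileext = ".csv")
    writeLines(c("cell,A,a", "c1,1,2"), dup)
    expect_error(loadExpression(dup), "duplicate gene")
})

test_that("MTX triplet loads to the same values as the equivalent CSV", {
    counts <- matrix(c(1, 0, 2, 3, 0, 5), nrow = 2,
        dimnames = list(c("A", "B"), c("c1", "c2", "c3")))
    dir <- tempfile(); dir.create(dir)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
        file.path(dir, "matrix.mtx"))
    writeLines(rownames(counts), file.path(dir, "features.tsv"))
    writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
    writeLines(c("barcode,celltype", "c1,alpha", "c2,beta", "c3,alpha"),
        file.path(dir, "obs.csv"))
    x <- loadExpression(dir, labelKey = "celltype")
    expect_equal(as.matrix(SummarizedExperiment::assay(x, "counts")),
        counts)
    expect_equal(x$label, c("alpha", "beta", "alpha"))
})

test_that("normalizeCells scales to the size factor then log1p", {
    m <- matrix(c(10, 30, 60), nrow = 1,
        dimnames = list("c1", c("A", "B", "C")))
    expect_equal(unname(normalizeCells(m, sizeFactor = 100)),
        log1p(matrix(c(10, 30, 60), 1)))
    m2 <- matrix(c(1, 1), nrow = 1, dimnames = list("c1", c("A", "B")))
    expect_equal(unname(drop(normalizeCells(m2))), rep(log1p(5000), 2))
    # all-zero cell: left at zero, with a warning
    m3 <- rbind(c1 = c(1, 1), c2 = c(0, 0))
    expect_warning(out <- normalizeCells(m3), "all-zero")
    expect_equal(unname(out["c2", ]), c(0, 0))
    # per-cell totals equal the size factor exactly after normalization
    counts <- matrix(rpois(200, 5) + 1, 10, 20,
        dimnames = list(sprintf("c%d", 1:10), sprintf("g%d", 1:20)))
    tot <- rowSums(expm1(normalizeCells(counts, sizeFactor = 1e4)))
    expect_equal(unname(tot), rep(1e4, 10), tolerance = 1e-9)
})

test_that("alignToVocabulary reorders, zero-fills and enforces overlap", {
    x <- matrix(c(5, 7), nrow = 1, dimnames = list("c1", c("B", "A")))
    out <- alignToVocabulary(x, c("A", "B", "C"))
    expect_equal(unname(drop(out)), c(7, 5, 0), ignore_attr = TRUE)
    expect_equal(attr(out, "overlap"), 2 / 3)

    idm <- alignToVocabulary(x, c("B", "A"))
    expect_equal(unname(idm), unname(x), ignore_attr = TRUE)

    expect_error(alignToVocabulary(x, c("X", "Y", "Z")), "disjoint")
})

test_that("normalize and align commute when no genes are dropped", {
    set.seed(1)
    for (rep in 1:5) {
        m <- matrix(rpois(30, 4), 5, 6,
            dimnames = list(sprintf("c%d", 1:5), sprintf("g%d", 1:6)))
        voc <- sample(colnames(m))
        a <- normalizeCells(alignToVocabulary(m, voc))
        b <- alignToVocabulary(normalizeCells(m), voc)
        expect_equal(unname(a), unname(b), tolerance = 1e-12)
    }
})

test_that("predictions CSV round-trips labels and probabilities", {
    probs <- matrix(c(0.97, 0.03, 0.4, 0.6), 2, byrow = TRUE,
        dimnames = list(c("c1", "c2"), c("alpha", "beta")))
    pred <- new("CellTypePrediction", probabilities = probs,
        predicted = c("alpha", "Unknown"), maxProb = c(0.97, 0.6),
        cutoff = 0.95)
    path <- tempfile(fileext = ".csv")
    writePredictions(pred, path)
    back <- read.csv(path, check.names = FALSE)
    expect_equal(back$predicted_label, c("alpha", "Unknown"))
    expect_equal(back$alpha, unname(probs[, "alpha"]), tolerance = 1e-6)
})
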
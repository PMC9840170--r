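test_that("readGMT parses sets, restricts to the vocabulary and errors on bad input", {
    path <- writeToyGMT(c("S1\tdesc\tA\tB", "S2\tdesc\tB\tC", "S3\tdesc\tC"))
    gsc <- readGMT(path, vocabulary = c("A", "B", "C"))
    expect_s4_class(gsc, "GeneSetCollection")
    expect_equal(lengths(geneSets(gsc)), c(S1 = 2L, S2 = 2L, S3 = 1L))

    # restriction drops genes outside the vocabulary, then empty sets
    gsc2 <- readGMT(path, vocabulary = c("A", "B"))
    expect_equal(names(geneSets(gsc2)), c("S1", "S2"))
    expect_equal(geneSets(gsc2)$S2, "B")

    one <- writeToyGMT("S1\tdesc\tX")
    expect_error(readGMT(one, vocabulary = c("A", "B")), "zero surviving")

    bad <- writeToyGMT(c("S1\tdesc\tA", "S2\tonlytwo"))
    expect_error(readGMT(bad), "line 2")

    # CRLF and trailing tabs are tolerated; matching is case-insensitive
    crlf <- writeToyGMT("S1\tdesc\ta\tB\t\r")
    expect_equal(geneSets(readGMT(crlf, vocabulary = c("A", "b")))$S1,
        c("a", "B"))
})

test_that("writeGMT round-trips a collection", {
    gsc <- smallSim()$geneSets
    path <- tempfile(fileext = ".gmt")
    writeGMT(gsc, path)
    back <- readGMT(path)
    expect_equal(geneSets(back), geneSets(gsc))
})

test_that("buildMask produces the membership matrix with size filters", {
    path <- writeToyGMT(c("S1\td\tA\tB", "S2\td\tB\tC", "S3\td\tC"))
    gsc <- readGMT(path, vocabulary = c("A", "B", "C"))
    mk <- buildMask(gsc, c("A", "B", "C"))
    M <- as.matrix(maskValues(mk))
    expect_equal(dim(M), c(3L, 3L))
    expect_equal(unname(colSums(M)), c(2, 2, 1))
    expect_equal(sum(M), 5)
    expect_equal(M["A", "S1"], 1)
    expect_equal(M["A", "S2"], 0)

    # maxSets keeps the largest sets
    mk2 <- buildMask(gsc, c("A", "B", "C"), maxSets = 2)
    expect_setequal(tokenNames(mk2), c("S1", "S2"))

    # oversize sets are dropped by default, truncated on request
    mk3 <- buildMask(gsc, c("A", "B", "C"), maxSetSize = 1)
    expect_equal(tokenNames(mk3), "S3")
    mk4 <- buildMask(gsc, c("A", "B", "C"), maxSetSize = 1,
        oversize = "truncate")
    expect_equal(ncol(maskValues(mk4)), 3L)
    expect_true(all(Matrix::colSums(maskValues(mk4)) == 1))

    expect_error(buildMask(gsc, c("A", "B", "C"), maxSetSize = 0),
        "zero gene sets")
})

test_that("buildMask is deterministic and column sums equal restricted set sizes", {
    gsc <- smallSim()$geneSets
    voc <- rownames(smallSim()$reference)
    m1 <- buildMask(gsc, voc)
    m2 <- buildMask(gsc, voc)
    expect_identical(as.matrix(maskValues(m1)), as.matrix(maskValues(m2)))
    sizes <- vapply(geneSets(gsc), function(g) sum(tolower(g) %in%
        tolower(voc)), numeric(1))
    expect_equal(unname(Matrix::colSums(maskValues(m1))[names(sizes)]),
        unname(sizes))
    # genes in no retained set keep an all-zero row (alignment stability)
    expect_equal(nrow(maskValues(m1)), length(voc))
})

test_that("randomMask draws reproducible columns of the forced size", {
    voc <- sprintf("g%03d", 1:100)
    mk <- randomMask(voc, k = 10, density = 0.05, seed = 3)
    expect_true(all(Matrix::colSums(maskValues(mk)) == 5))
    mk2 <- randomMask(voc, k = 10, density = 0.05, seed = 3)
    expect_identical(as.matrix(maskValues(mk)), as.matrix(maskValues(mk2)))
    mk3 <- randomMask(voc, k = 10, density = 0.05, seed = 4)
    expect_false(identical(as.matrix(maskValues(mk)),
        as.matrix(maskValues(mk3))))

    # ceiling(0.01 * 200) = 2 ones per column
    mk4 <- randomMask(sprintf("g%d", 1:200), k = 300, density = 0.01,
        seed = 1)
    expect_equal(dim(maskValues(mk4)), c(200L, 300L))
    expect_true(all(Matrix::colSums(maskValues(mk4)) == 2))

    expect_error(randomMask(voc, k = 5, density = 0), "density")
    expect_error(randomMask(voc, k = 5, density = 1.2), "density")
})

test_that("mask TSV export/import round-trips", {
    mk <- smallMask()
    path <- tempfile(fileext = ".tsv")
    exportMask(mk, path)
    back <- importMask(path)
    expect_equal(as.matrix(maskValues(back)), as.matrix(maskValues(mk)))
    expect_equal(back@provenance, mk@provenance)
})
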
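# Shared fixtures, built once per test run. Everything is generated in
# code; no on-disk data.
.fixtures <- new.env(parent = emptyenv())

# Small pathway-driven dataset: 3 types, 6 pathways (3 unused), 120 genes.
smallSim <- function() {
    if (is.null(.fixtures$sim))
        .fixtures$sim <- simulatePathwayData(nGenes = 120, nRef = 300,
            nQuery = 150, nTypes = 3, nPathways = 6, genesPerPathway = 20,
            seed = 42)
    .fixtures$sim
}

smallMask <- function() {
    if (is.null(.fixtures$mask))
        .fixtures$mask <- buildMask(smallSim()$geneSets,
            rownames(smallSim()$reference))
    .fixtures$mask
}

# A quickly trained model on the small dataset, reused across test files.
smallModel <- function() {
    if (is.null(.fixtures$model))
        .fixtures$model <- trainModel(smallSim()$reference, smallMask(),
            config = modelConfig(m = 16, H = 2, seed = 11),
            training = trainConfig(epochs = 8, batchSize = 32, seed = 13))
    .fixtures$model
}

# Untrained seeded model on a fixed 6-gene / 3-set / m = 4 / H = 2
# instance, for equation-level oracles.
tinyInstance <- function(seed = 11) {
    gsc <- new("GeneSetCollection",
        sets = list(S1 = c("g1", "g2", "g3"), S2 = c("g3", "g4"),
            S3 = c("g5", "g6")),
        provenance = "toy")
    mask <- buildMask(gsc, sprintf("g%d", 1:6))
    cfg <- modelConfig(m = 4L, H = 2L, depth = 1L, seed = seed)
    cfg$normalize <- FALSE
    cfg$sizeFactor <- 1e4
    params <- pathattn:::.initParams(mask, 2L, cfg)
    model <- new("TokenTransformer", mask = mask, params = params,
        labels = c("A", "B"), config = cfg,
        history = data.frame())
    list(mask = mask, cfg = cfg, params = params, model = model)
}

writeToyGMT <- function(lines) {
    path <- tempfile(fileext = ".gmt")
    writeLines(lines, path)
    path
}

# SingleCellExperiment from a cells x genes count matrix.
sceFromCounts <- function(counts, label = NULL) {
    cd <- if (is.null(label))
        S4Vectors::DataFrame(row.names = rownames(counts))
    else S4Vectors::DataFrame(label = label, row.names = rownames(counts))
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = t(counts)), colData = cd)
}
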
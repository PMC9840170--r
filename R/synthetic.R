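#' Simulate pathway-driven labeled scRNA-seq counts
#'
#' Generates a reference/query pair of negative-binomial count matrices in
#' which cell types are separable purely through gene-set (pathway)
#' activity — the structure the masked-embedding model assumes. The gene
#' space is partitioned into \code{nPathways} disjoint sets of
#' \code{genesPerPathway} genes; each cell type activates one driver
#' pathway (type i drives pathway i), whose member genes have their mean
#' multiplied by \code{effect}. Per-cell library sizes are log-normal;
#' optional batches multiply every gene's mean by a gene-wise log-normal
#' factor that is independent of the cell type (a pure technical effect).
#' A ground-truth \linkS4class{GeneSetCollection} is emitted for building
#' the mask.
#'
#' Defaults describe the desk-scale validation world used throughout the
#' package: 5 types, 500 genes, 20 pathways (so 15 pathways drive no type),
#' 2000 reference + 1000 query cells, effect 3.0 over a baseline mean of
#' 0.5, negative-binomial dispersion 0.3, library-size log-sd 0.3, batch
#' log-sd 0.2.
#'
#' @param nGenes number of genes (default 500).
#' @param nRef,nQuery reference / query cell counts (defaults 2000, 1000).
#' @param nTypes number of cell types (default 5).
#' @param nPathways number of gene sets (default 20; must be >=
#'   \code{nTypes} and satisfy
#'   \code{nPathways * genesPerPathway <= nGenes}).
#' @param genesPerPathway member genes per set (default 25).
#' @param effect multiplicative mean shift for driver-set genes in their
#'   type (default 3.0); 1.0 removes all signal.
#' @param baseline baseline negative-binomial mean per gene (default 0.5).
#' @param dispersion negative-binomial dispersion (variance =
#'   \code{mu + dispersion * mu^2}; default 0.3).
#' @param libsizeSigma log-sd of the per-cell library-size factor
#'   (default 0.3).
#' @param nBatches number of batches in the query (default 1 = no batch
#'   structure).
#' @param batchSigma log-sd of the gene-wise batch factors (default 0.2).
#' @param holdoutType optional type name (e.g. \code{"T5"}) excluded from
#'   the reference but present in the query, for novel-type experiments.
#' @param seed integer seed; the same seed reproduces identical counts.
#' @return list with \code{reference} and \code{query}
#'   (\code{SingleCellExperiment}s with \code{label}, and \code{batch} on
#'   the query), \code{geneSets} (truth \linkS4class{GeneSetCollection}),
#'   and \code{drivers} (named character: type -> driver pathway).
#' @export
simulatePathwayData <- function(nGenes = 500L, nRef = 2000L,
        nQuery = 1000L, nTypes = 5L, nPathways = 20L,
        genesPerPathway = 25L, effect = 3.0, baseline = 0.5,
        dispersion = 0.3, libsizeSigma = 0.3, nBatches = 1L,
        batchSigma = 0.2, holdoutType = NULL, seed = 1L) {
    bad <- character()
    if (nTypes < 2L) bad <- c(bad, "nTypes must be >= 2")
    if (nPathways < nTypes)
        bad <- c(bad, "need at least one pathway per type")
    if (nPathways * genesPerPathway > nGenes)
        bad <- c(bad, "nPathways * genesPerPathway exceeds nGenes")
    if (effect <= 0 || baseline <= 0 || dispersion <= 0)
        bad <- c(bad, "effect, baseline and dispersion must be positive")
    if (length(bad)) stop("invalid simulation spec: ",
        paste(bad, collapse = "; "))
    genes <- sprintf("G%04d", seq_len(nGenes))
    pwNames <- sprintf("PW%02d", seq_len(nPathways))
    types <- sprintf("T%d", seq_len(nTypes))
    sets <- lapply(seq_len(nPathways), function(j)
        genes[((j - 1L) * genesPerPathway + 1L):(j * genesPerPathway)])
    names(sets) <- pwNames
    drivers <- stats::setNames(pwNames[seq_len(nTypes)], types)
    if (!is.null(holdoutType) && !holdoutType %in% types)
        stop("holdoutType '", holdoutType, "' is not one of the types")

    .withSeed(seed, {
        refTypes <- if (is.null(holdoutType)) types
            else setdiff(types, holdoutType)
        refLab <- rep(refTypes, length.out = nRef)
        qLab <- rep(types, length.out = nQuery)
        # random batch assignment so batch is independent of cell type
        qBatch <- sample(rep(sprintf("B%d", seq_len(nBatches)),
            length.out = nQuery))
        batchFac <- matrix(1, nGenes, nBatches)
        if (nBatches > 1L)
            batchFac <- matrix(exp(stats::rnorm(nGenes * nBatches, 0,
                batchSigma)), nGenes, nBatches)
        draw <- function(lab, batch = NULL) {
            ncell <- length(lab)
            lib <- exp(stats::rnorm(ncell, 0, libsizeSigma))
            counts <- matrix(0L, nGenes, ncell,
                dimnames = list(genes,
                    sprintf("c%05d", seq_len(ncell))))
            for (i in seq_len(ncell)) {
                mu <- rep(baseline, nGenes)
                drv <- sets[[drivers[[lab[i]]]]]
                mu[match(drv, genes)] <- baseline * effect
                if (!is.null(batch))
                    mu <- mu * batchFac[, as.integer(sub("B", "",
                        batch[i]))]
                mu <- mu * lib[i]
                counts[, i] <- stats::rnbinom(nGenes, mu = mu,
                    size = 1 / dispersion)
            }
            counts
        }
        refCounts <- draw(refLab)
        colnames(refCounts) <- sprintf("ref%05d", seq_len(nRef))
        qCounts <- draw(qLab, batch = qBatch)
        colnames(qCounts) <- sprintf("qry%05d", seq_len(nQuery))
        reference <- SingleCellExperiment::SingleCellExperiment(
            assays = list(counts = refCounts),
            colData = S4Vectors::DataFrame(label = refLab,
                row.names = colnames(refCounts)))
        query <- SingleCellExperiment::SingleCellExperiment(
            assays = list(counts = qCounts),
            colData = S4Vectors::DataFrame(label = qLab, batch = qBatch,
                row.names = colnames(qCounts)))
        list(reference = reference, query = query,
            geneSets = new("GeneSetCollection", sets = sets,
                provenance = "simulated"),
            drivers = drivers)
    })
}
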
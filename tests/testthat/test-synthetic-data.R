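test_that("simulation is bit-identical under a fixed seed and differs across seeds", {
    cfg <- tinyConfig(seed = 1L)
    a <- simulateCAFDataset(cfg)
    b <- simulateCAFDataset(cfg)
    expect_identical(counts(a), counts(b))
    expect_identical(colData(a), colData(b))
    c2 <- simulateCAFDataset(tinyConfig(seed = 2L))
    expect_false(identical(counts(a), counts(c2)))
    ## identical truth schema regardless of seed
    expect_identical(S4Vectors::metadata(a)$truth$markerTable,
                     S4Vectors::metadata(c2)$truth$markerTable)

    bk1 <- simulateBulkExperiment(nGenes = 200L, nDE = 10L, seed = 3L)
    bk1b <- simulateBulkExperiment(nGenes = 200L, nDE = 10L, seed = 3L)
    bk2 <- simulateBulkExperiment(nGenes = 200L, nDE = 10L, seed = 4L)
    expect_identical(bk1$counts, bk1b$counts)
    expect_false(identical(bk1$counts, bk2$counts))
    expect_identical(bk1$truth, bk2$truth)
})

test_that("invalid configurations are rejected", {
    expect_error(simConfig(nbDispersion = 0), "positive")
    expect_error(simConfig(markerPlan = data.frame(
        gene = "G0001", population = "CP", foldChange = 0.5)), "foldChange")
    expect_error(simConfig(markerPlan = data.frame(
        gene = "G0001", population = "nope", foldChange = 2)),
        "populationTree")
})

test_that("marker genes reach the planted fold-change in their population", {
    ## Monte-Carlo check against the NB moments at the study's default scale
    cfg <- simConfig(seed = 42L)   # 2000 genes, 6 x 300 cells, FC 8 markers
    sce <- simulateCAFDataset(cfg)
    mk <- S4Vectors::metadata(sce)$truth$markerTable
    cts <- counts(sce)
    for (pop in c("CP", "CtrII")) {
        genes <- mk$gene[mk$population == pop][1:10]
        inPop <- sce$subPop == pop
        mIn <- Matrix::rowMeans(cts[genes, inPop, drop = FALSE])
        mOut <- Matrix::rowMeans(cts[genes, !inPop, drop = FALSE])
        vIn <- apply(as.matrix(cts[genes, inPop, drop = FALSE]), 1, var)
        vOut <- apply(as.matrix(cts[genes, !inPop, drop = FALSE]), 1, var)
        se <- sqrt(vIn / sum(inPop) + 64 * vOut / sum(!inPop))
        expect_true(all(abs(mIn - 8 * mOut) < 3 * se))
    }
})

test_that("a flat fold-change plan leaves populations unseparated", {
    cfg <- simConfig(nGenes = 300L, nCellsPerSample = 320L, nSamples = 1L,
                     markerPlan = data.frame(
                         gene = sprintf("G%04d", 1:40),
                         population = rep(c("CP", "CS", "CtrI", "CtrII"), 10),
                         foldChange = 1),
                     seed = 50L)
    sce <- simulateCAFDataset(cfg)
    m <- as.matrix(counts(sce))
    popMeans <- sapply(split(seq_len(ncol(m)), sce$subPop),
                       function(idx) mean(m[1:40, idx]))
    expect_lt(max(popMeans) / min(popMeans), 1.2)
})

test_that("atlas populations over-express their planted markers", {
    atl <- simulateReferenceAtlas(simConfig(nCellsPerSample = 150L,
                                            seed = 6L))
    mk <- S4Vectors::metadata(atl)$truth$markerTable
    cts <- counts(atl)
    for (pop in unique(mk$population)) {
        genes <- mk$gene[mk$population == pop]
        byPop <- sapply(split(seq_len(ncol(cts)), atl$population),
                        function(idx)
                            mean(Matrix::rowMeans(cts[genes, idx,
                                                      drop = FALSE])))
        expect_identical(names(which.max(byPop)), pop)
    }
})

test_that("atlas marker sharing follows the origin map", {
    cfg <- tinyConfig(seed = 7L)
    caf <- simulateCAFDataset(cfg)
    cafMk <- S4Vectors::metadata(caf)$truth$markerTable
    atl <- simulateReferenceAtlas(simConfig(nGenes = 300L,
                                            nCellsPerSample = 30L, seed = 8L),
                                  cafMarkers = cafMk, sharedFraction = 0.5)
    atlMk <- S4Vectors::metadata(atl)$truth$markerTable
    cpShared <- intersect(cafMk$gene[cafMk$population == "CP"],
                          atlMk$gene[atlMk$population == "SAMes"])
    expect_length(cpShared, 15L)   # floor(0.5 * 30)
    ## no sharing -> atlas markers disjoint from CAF markers
    atl0 <- simulateReferenceAtlas(simConfig(nGenes = 300L,
                                             nCellsPerSample = 30L,
                                             seed = 8L),
                                   cafMarkers = cafMk, sharedFraction = 0)
    mk0 <- S4Vectors::metadata(atl0)$truth$markerTable
    expect_length(intersect(mk0$gene, cafMk$gene), 0L)
})

test_that("10x MTX triplets round-trip exactly", {
    m <- Matrix(matrix(c(5L, 0L, 2L, 0L, 0L, 1L, 7L, 0L, 0L, 0L, 0L, 3L,
                         0L, 0L, 0L, 4L, 9L, 0L, 0L, 6L), 5, 4,
                       dimnames = list(paste0("G", 1:5), paste0("C", 1:4))),
                sparse = TRUE)
    d <- withr::local_tempdir()
    write10xMTX(m, d)
    r <- read10xMTX(d)
    expect_identical(as.matrix(r), as.matrix(m))
    expect_identical(dimnames(r), dimnames(m))

    ## zero row and zero column are preserved
    z <- m; z[2, ] <- 0; z[, 3] <- 0
    z <- drop0(z)
    d2 <- withr::local_tempdir()
    write10xMTX(z, d2)
    expect_identical(as.matrix(read10xMTX(d2)), as.matrix(z))

    ## empty matrix round-trips to the same dimensions
    e <- Matrix(0, 3, 0, dimnames = list(paste0("G", 1:3), NULL))
    d3 <- withr::local_tempdir()
    write10xMTX(e, d3)
    r3 <- read10xMTX(d3)
    expect_identical(dim(r3), c(3L, 0L))
    expect_identical(rownames(r3), rownames(e))
})

test_that("interaction truth plants the requested pair classes", {
    cfg <- simConfig(nGenes = 800L, nCellsPerSample = 20L, nSamples = 2L,
                     seed = 9L)
    lrt <- simulateLRTruth(cfg, nBiasedA = 2L, nBiasedB = 3L,
                           nReliable = 4L, nNull = 5L)
    expect_identical(nrow(lrt$pairs), 14L)
    expect_identical(as.vector(table(lrt$pairs$class)[
        c("biased_Ctr", "biased_ECM", "null", "reliable")]),
        c(3L, 2L, 5L, 4L))
    ## null pairs have no expression plan entries
    nullLig <- lrt$pairs$ligand[lrt$pairs$class == "null"]
    expect_false(any(nullLig %in% lrt$plan$gene))
    ## ligand and receptor identifiers never collide
    expect_length(intersect(lrt$pairs$ligand, lrt$pairs$receptor), 0L)
})
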
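test_that("the interaction score matches its closed form", {
    expect_identical(lrScore(1, 1, 1), 0.5)
    expect_identical(lrScore(0, 5, 1), 0)
    expect_identical(lrScore(3, 0, 2), 0)
    expect_equal(lrScore(4, 1, 1), 2 / 3)

    ## random grid against the formula
    set.seed(1)
    l <- runif(200, 0, 10); r <- runif(200, 0, 10); mu <- runif(200, .1, 5)
    expect_lt(max(abs(lrScore(l, r, mu) -
                      sqrt(l * r) / (mu + sqrt(l * r)))), 1e-12)
    expect_true(all(lrScore(l, r, mu) >= 0 & lrScore(l, r, mu) < 1))

    ## monotone non-decreasing in l and r
    ls <- seq(0, 10, length.out = 50)
    expect_false(is.unsorted(lrScore(ls, 2, 1)))
    expect_false(is.unsorted(lrScore(2, ls, 1)))

    expect_error(lrScore(-1, 1, 1))
    expect_error(lrScore(1, 1, 0))
})

## a fully controlled experiment: assign logcounts directly
mkLRSce <- function(vals, samples, pops) {
    sce <- SingleCellExperiment(assays = list(
        counts = as(vals, "CsparseMatrix"),
        logcounts = as(vals, "CsparseMatrix")),
        colData = S4Vectors::DataFrame(sample = samples, population = pops,
                                       row.names = colnames(vals)))
    sce
}

test_that("identical samples give identical per-sample scores", {
    genes <- c("L1", "R1", "other")
    oneSample <- cbind(matrix(c(4, 0, 1), 3, 12),   # source population
                       matrix(c(0, 4, 1), 3, 12))   # target population
    vals <- cbind(oneSample, oneSample, oneSample)
    rownames(vals) <- genes
    colnames(vals) <- sprintf("c%02d", seq_len(ncol(vals)))
    samples <- rep(c("S1", "S2", "S3"), each = 24)
    pops <- rep(rep(c("src", "tgt"), each = 12), 3)
    sce <- mkLRSce(vals, samples, pops)
    rec <- scoreLRInteractions(sce, data.frame(ligand = "L1",
                                               receptor = "R1"),
                               sources = "src", targets = "tgt",
                               minCells = 5L)
    sc <- unlist(rec[1, paste0("score_", c("S1", "S2", "S3"))])
    expect_equal(unname(sc), rep(sc[[1]], 3))
    expect_identical(rec$nSamples, 3L)
})

test_that("pairs with absent genes are skipped and low-cell samples excluded", {
    genes <- c("L1", "R1")
    vals <- matrix(2, 2, 30, dimnames = list(genes, sprintf("c%02d", 1:30)))
    samples <- c(rep("S1", 24), rep("S2", 6))
    pops <- c(rep(c("src", "tgt"), each = 12), rep(c("src", "tgt"), 3))
    sce <- mkLRSce(vals, samples, pops)
    pairs <- data.frame(ligand = c("L1", "L1"), receptor = c("R1", "Rmissing"))
    rec <- scoreLRInteractions(sce, pairs, sources = "src", targets = "tgt",
                               minCells = 10L)
    expect_identical(nrow(rec), 1L)
    expect_identical(attr(rec, "skippedPairs")$receptor, "Rmissing")
    ## S2 has 3 cells per population -> excluded from the median
    expect_identical(rec$nSamples, 1L)
    expect_true(is.na(rec$score_S2))
})

test_that("reliability requires a median strictly above 0.5", {
    rec <- data.frame(ligand = "L1", receptor = "R1", source = "A",
                      target = "T", median = 0.5, nSamples = 6L,
                      reliable = 0.5 > 0.5)
    expect_false(rec$reliable)
    m <- countInteractions(rec)
    expect_identical(m["A", "T"], 0L)
})

test_that("interaction counting is order invariant and zero on empty input", {
    rec <- data.frame(
        ligand = paste0("L", 1:4), receptor = paste0("R", 1:4),
        source = c("CAF", "CAF", "Cancer", "CAF"),
        target = c("Cancer", "Cancer", "CAF", "Cancer"),
        median = c(0.7, 0.8, 0.6, 0.4), nSamples = 6L,
        reliable = c(TRUE, TRUE, TRUE, FALSE))
    m1 <- countInteractions(rec)
    m2 <- countInteractions(rec[sample(4), ])
    expect_identical(m1, m2)
    expect_identical(m1["CAF", "Cancer"], 2L)
    expect_identical(m1["Cancer", "CAF"], 1L)
    none <- countInteractions(rec[rec$median > 1, ])
    expect_true(all(none == 0L))
})

test_that("bias selection applies strict threshold and DE gates", {
    mk <- function(med) data.frame(
        ligand = paste0("L", 1:5), receptor = paste0("R", 1:5),
        source = "A", target = "T", median = med, nSamples = 6L,
        reliable = med > 0.5)
    recA <- mk(c(0.70, 0.70, 0.70, 0.60, 0.45))
    recB <- mk(c(0.60, 0.40, 0.40, 0.58, 0.30))
    ## L1: delta exactly 0.1 -> excluded; L2: DE padj too large -> excluded;
    ## L3: passes; L4: delta 0.02 -> excluded; L5: not reliable -> excluded
    de <- mkDE(paste0("L", 1:5),
               log2FC = c(3, 3, 3, 3, 3),
               padj = c(1e-5, 0.02, 1e-5, 1e-5, 1e-5))
    bi <- biasedInteractions(recA, recB, de)
    expect_identical(bi$A$ligand, "L3")
    expect_identical(nrow(bi$B), 0L)
    ## disjoint by construction
    expect_length(intersect(bi$A$ligand, bi$B$ligand), 0L)

    ## FC gate is strict: FC exactly 2 fails
    de2 <- mkDE(paste0("L", 1:5), log2FC = 1, padj = 1e-5)
    bi2 <- biasedInteractions(recA, recB, de2)
    expect_identical(nrow(bi2$A), 0L)

    ## symmetric direction: ligand DE toward B
    de3 <- mkDE(paste0("L", 1:5), log2FC = -3, padj = 1e-5)
    recB2 <- mk(c(0.70, 0.70, 0.85, 0.58, 0.30))
    recA2 <- mk(c(0.60, 0.40, 0.40, 0.56, 0.30))
    ## L1 sits at delta exactly 0.1 -> excluded; L2 and L3 pass
    bi3 <- biasedInteractions(recA2, recB2, de3)
    expect_setequal(bi3$B$ligand, c("L2", "L3"))
})

test_that("planted biases are recovered end to end at default thresholds", {
    cfg <- simConfig(nGenes = 800L, nCellsPerSample = 60L, nSamples = 4L,
                     seed = 13L)
    lrt <- simulateLRTruth(cfg, nBiasedA = 3L, nBiasedB = 3L,
                           nReliable = 4L, nNull = 10L)
    sce <- normalizeLog(simulateInteractionDataset(cfg, lrt))
    rec <- scoreLRInteractions(sce, lrt$pairs, sources = c("ECM", "Ctr"),
                               targets = "Cancer")
    de <- deBetween(sce, "population", "ECM", "Ctr")
    recA <- rec[rec$source == "ECM", ]
    recB <- rec[rec$source == "Ctr", ]
    bi <- biasedInteractions(recA, recB, de)
    truthA <- lrt$pairs$ligand[lrt$pairs$class == "biased_ECM"]
    truthB <- lrt$pairs$ligand[lrt$pairs$class == "biased_Ctr"]
    expect_setequal(bi$A$ligand, truthA)
    expect_setequal(bi$B$ligand, truthB)
    ## reliable-but-unbiased pairs pass the median gate in both directions
    relLig <- lrt$pairs$ligand[lrt$pairs$class == "reliable"]
    expect_true(all(recA$reliable[recA$ligand %in% relLig]))
    expect_true(all(recB$reliable[recB$ligand %in% relLig]))
})
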
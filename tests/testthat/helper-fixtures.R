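## Shared fixtures and independent oracle implementations.
## Oracles are deliberately naive re-implementations kept separate from the
## package code paths they check.

suppressPackageStartupMessages({
    library(Matrix)
    library(SingleCellExperiment)
})

nestedTree <- list(ECM = c("CP", "CS"), Ctr = c("CtrI", "CtrII"))

tinyConfig <- function(nGenes = 300L, nCellsPerSample = 60L, nSamples = 2L,
                       seed = 1L, ...) {
    simConfig(nGenes = nGenes, nCellsPerSample = nCellsPerSample,
              nSamples = nSamples,
              markerPlan = defaultMarkerPlan(nGenes, nestedTree),
              seed = seed, ...)
}

## SingleCellExperiment straight from a dense count matrix
sceFromCounts <- function(m, ...) {
    SingleCellExperiment(
        assays = list(counts = as(as(m, "CsparseMatrix"), "generalMatrix")),
        colData = S4Vectors::DataFrame(..., row.names = colnames(m)))
}

## Brute-force BH step-up definition: adj_i = min_{j >= i} min(1, m p_(j) / j)
bruteBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- pmin(1, m * p[ord] / seq_len(m))
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[ord] <- adj
    out
}

## Exhaustive hypergeometric: P(|B' & A| >= k) over all size-b subsets B'
## of a universe of size N, A fixed of size a. Feasible for N <= 12.
bruteHyperTail <- function(k, a, b, N) {
    hits <- 0L; total <- 0L
    for (idx in utils::combn(N, b, simplify = FALSE)) {
        total <- total + 1L
        if (sum(idx <= a) >= k) hits <- hits + 1L
    }
    hits / total
}

## Naive TMM re-implementation (weighted trimmed mean of M-values against a
## reference library), independent of edgeR.
naiveTMM <- function(counts, refCol = NULL, logratioTrim = 0.3,
                     sumTrim = 0.05) {
    lib <- colSums(counts)
    q75 <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
    if (is.null(refCol)) refCol <- which.min(abs(q75 - mean(q75)))
    f <- vapply(seq_len(ncol(counts)), function(i) {
        obs <- counts[, i] / lib[i]
        ref <- counts[, refCol] / lib[refCol]
        keep <- obs > 0 & ref > 0
        obs <- obs[keep]; ref <- ref[keep]
        M <- log2(obs / ref)
        A <- (log2(obs) + log2(ref)) / 2
        w <- (1 - counts[keep, i] / lib[i]) / counts[keep, i] +
            (1 - counts[keep, refCol] / lib[refCol]) / counts[keep, refCol]
        ## rank-based double trimming of M and A
        nn <- length(M)
        loM <- floor(nn * logratioTrim) + 1; hiM <- nn + 1 - loM
        loA <- floor(nn * sumTrim) + 1; hiA <- nn + 1 - loA
        keep2 <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
        2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
    }, numeric(1))
    f / exp(mean(log(f)))
}

## Construct a DEResult directly (for unit-testing the signature rules
## without running the DE engine)
mkDE <- function(genes, log2FC, padj, fracA = 1, fracB = 0.5,
                 groupA = "A", groupB = "B") {
    n <- length(genes)
    new("DEResult",
        S4Vectors::DataFrame(
            log2FC = rep_len(log2FC, n), pvalue = rep_len(padj, n),
            padj = rep_len(padj, n), fracA = rep_len(fracA, n),
            fracB = rep_len(fracB, n), meanA = rep_len(1, n),
            meanB = rep_len(1, n), allZero = rep_len(FALSE, n),
            row.names = genes),
        groupA = groupA, groupB = groupB)
}
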
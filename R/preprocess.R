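#' Quality-control and normalization parameters
#'
#' Defaults follow the study protocol: within each sample the cells in the
#' top 0.05\% of total UMIs are treated as doublets; cells with fewer than
#' 1,000 distinct genes are discarded; each transcriptome is scaled to
#' 10,000 total counts and log2-transformed; the 1,500 most variable genes
#' (coefficient of variation) among the 5,000 most expressed genes, over
#' genes detected in at least 1\% of cells, define the variable-gene space.
#'
#' @slot doubletTopFraction fraction of top-UMI cells removed per sample.
#' @slot minGenes minimum number of distinct detected genes per cell.
#' @slot scaleTotal per-cell total after normalization.
#' @slot nTopExpressed pool of most-expressed genes considered.
#' @slot nVariable number of variable genes retained.
#' @slot minCellFraction minimum detection fraction per gene.
#' @slot cvScale `"linear"` (default) or `"log"`: scale on which the
#'   coefficient of variation is computed.
#' @export
setClass("QCParams", representation(
    doubletTopFraction = "numeric",
    minGenes = "integer",
    scaleTotal = "numeric",
    nTopExpressed = "integer",
    nVariable = "integer",
    minCellFraction = "numeric",
    cvScale = "character"
))

setValidity("QCParams", function(object) {
    msg <- character()
    if (object@doubletTopFraction < 0 || object@doubletTopFraction >= 1)
        msg <- c(msg, "doubletTopFraction must be in [0, 1)")
    if (object@nVariable > object@nTopExpressed)
        msg <- c(msg, "nVariable must be <= nTopExpressed")
    if (!object@cvScale %in% c("linear", "log"))
        msg <- c(msg, "cvScale must be 'linear' or 'log'")
    if (length(msg)) msg else TRUE
})

#' @describeIn QCParams Constructor.
#' @param doubletTopFraction,minGenes,scaleTotal,nTopExpressed,nVariable,
#'   minCellFraction,cvScale see slots.
#' @export
qcParams <- function(doubletTopFraction = 5e-4, minGenes = 1000L,
                     scaleTotal = 1e4, nTopExpressed = 5000L,
                     nVariable = 1500L, minCellFraction = 0.01,
                     cvScale = "linear") {
    new("QCParams",
        doubletTopFraction = doubletTopFraction,
        minGenes = as.integer(minGenes),
        scaleTotal = scaleTotal,
        nTopExpressed = as.integer(nTopExpressed),
        nVariable = as.integer(nVariable),
        minCellFraction = minCellFraction,
        cvScale = cvScale)
}

#' @export
setMethod("show", "QCParams", function(object) {
    cat(sprintf(paste0("QCParams: doublet top %.3g%%/sample, >=%d genes/cell,",
                       " scale %g,\n  %d variable of %d expressed genes",
                       " (>= %.3g%% of cells), CV on %s scale\n"),
                100 * object@doubletTopFraction, object@minGenes,
                object@scaleTotal, object@nVariable, object@nTopExpressed,
                100 * object@minCellFraction, object@cvScale))
})

#' Remove putative doublets by top total UMI per sample
#'
#' Within each sample, the `ceiling(doubletTopFraction * n_cells)` cells
#' with the highest total UMI count are removed. Ties at the quota
#' boundary are broken by barcode order (the lexicographically smaller
#' barcode is removed), making the filter deterministic.
#'
#' @param sce a `SingleCellExperiment` with a raw `counts` assay and a
#'   `colData` column naming the sample of origin.
#' @param params a [QCParams-class] object.
#' @param sampleCol name of the sample column in `colData`.
#' @return The filtered `SingleCellExperiment`; barcodes of removed cells
#'   are recorded in `metadata(sce)$removedDoublets`.
#' @export
removeDoubletsTopUMI <- function(sce, params = qcParams(),
                                 sampleCol = "sample") {
    stopifnot(is(params, "QCParams"))
    if (!sampleCol %in% colnames(colData(sce)) ||
        anyNA(colData(sce)[[sampleCol]]))
        stop("every cell must have a sample id in colData$", sampleCol)
    totals <- Matrix::colSums(counts(sce))
    samples <- colData(sce)[[sampleCol]]
    removed <- character()
    for (s in unique(samples)) {
        idx <- which(samples == s)
        quota <- ceiling(params@doubletTopFraction * length(idx))
        if (quota == 0L) next
        ord <- idx[order(-totals[idx], colnames(sce)[idx])]
        removed <- c(removed, colnames(sce)[ord[seq_len(quota)]])
    }
    out <- sce[, !colnames(sce) %in% removed]
    S4Vectors::metadata(out)$removedDoublets <- removed
    out
}

#' Discard cells with too few distinct detected genes
#'
#' Keeps cells in which at least `minGenes` genes have a positive count
#' (a cell with exactly `minGenes` detected genes is kept).
#'
#' @inheritParams removeDoubletsTopUMI
#' @return The filtered `SingleCellExperiment`; an all-cells-removed
#'   outcome yields an empty object with a warning, not an error.
#' @export
filterMinGenes <- function(sce, params = qcParams()) {
    stopifnot(is(params, "QCParams"))
    detected <- Matrix::colSums(counts(sce) > 0)
    keep <- detected >= params@minGenes
    if (!any(keep))
        warning("all cells fall below the minimum detected-gene threshold")
    sce[, keep]
}

#' Total-count normalization and log2 transform
#'
#' Each cell is divided by its total UMI count, multiplied by
#' `scaleTotal` (10,000 by default) and transformed as
#' `log2(1 + x)`. Stored in the `logcounts` assay (sparse).
#'
#' @inheritParams removeDoubletsTopUMI
#' @return `sce` with a `logcounts` assay added.
#' @export
normalizeLog <- function(sce, params = qcParams()) {
    stopifnot(is(params, "QCParams"))
    cts <- counts(sce)
    totals <- Matrix::colSums(cts)
    if (any(totals <= 0))
        stop("cells with zero total counts cannot be normalized")
    norm <- methods::as(cts, "CsparseMatrix")
    norm@x <- norm@x * rep.int(params@scaleTotal / totals, diff(norm@p))
    norm@x <- log2(1 + norm@x)
    logcounts(sce) <- norm
    sce
}

#' Select variable genes by coefficient of variation
#'
#' Three-step selection on the normalized (linear-scale) expression:
#' genes detected (raw count > 0) in at least `minCellFraction` of cells
#' are eligible; of these, the `nTopExpressed` genes with highest mean
#' expression are kept; among them, the `nVariable` genes with the highest
#' coefficient of variation (sd/mean) are returned, sorted by CV
#' descending. Setting `cvScale = "log"` computes mean and CV on the
#' log-normalized values instead.
#'
#' @param sce a `SingleCellExperiment` with `counts` and `logcounts`.
#' @param params a [QCParams-class] object.
#' @return Character vector of gene names, CV-descending. If fewer than
#'   `nVariable` genes are eligible, all eligible genes are returned with
#'   a warning.
#' @export
selectVariableGenes <- function(sce, params = qcParams()) {
    stopifnot(is(params, "QCParams"))
    n <- ncol(sce)
    detFrac <- Matrix::rowSums(counts(sce) > 0) / n
    vals <- logcounts(sce)
    if (params@cvScale == "linear") {
        vals <- methods::as(vals, "CsparseMatrix")
        vals@x <- 2^vals@x - 1
    }
    mu <- Matrix::rowMeans(vals)
    ## E[x^2] on sparse values; sample variance with n-1 denominator
    sq <- vals; sq@x <- sq@x^2
    ex2 <- Matrix::rowMeans(sq)
    v <- pmax(ex2 - mu^2, 0) * n / max(n - 1L, 1L)
    cv <- ifelse(mu > 0, sqrt(v) / mu, 0)
    eligible <- which(detFrac >= params@minCellFraction)
    topExpr <- eligible[order(-mu[eligible], rownames(sce)[eligible])]
    topExpr <- utils::head(topExpr, params@nTopExpressed)
    if (length(topExpr) < params@nVariable)
        warning("fewer eligible genes than requested; returning all ",
                length(topExpr))
    sel <- topExpr[order(-cv[topExpr], rownames(sce)[topExpr])]
    sel <- utils::head(sel, params@nVariable)
    rownames(sce)[sel]
}

#' Run the full QC + normalization + gene-selection stage
#'
#' Applies, in protocol order, per-sample doublet removal, the
#' distinct-gene filter, total-count log-normalization, and variable-gene
#' selection.
#'
#' @inheritParams removeDoubletsTopUMI
#' @return The processed `SingleCellExperiment`; the selected genes are in
#'   `metadata(sce)$variableGenes`.
#' @export
preprocessCells <- function(sce, params = qcParams(), sampleCol = "sample") {
    sce <- removeDoubletsTopUMI(sce, params, sampleCol)
    sce <- filterMinGenes(sce, params)
    sce <- normalizeLog(sce, params)
    S4Vectors::metadata(sce)$variableGenes <- selectVariableGenes(sce, params)
    sce
}
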
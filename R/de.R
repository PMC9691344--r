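#' @importFrom stats p.adjust model.matrix pchisq phyper
NULL

#' TMM between-library normalization factors
#'
#' Trimmed-mean-of-M-values scale factors (M trim 0.30, A trim 0.05,
#' precision weights; the reference library is the one whose upper
#' quartile is closest to the mean upper quartile), normalized so the
#' factors multiply to 1 (geometric mean 1).
#'
#' @param counts genes x libraries matrix of raw counts (cells or bulk
#'   replicates as libraries).
#' @return Named numeric vector of factors, one per library.
#' @export
tmmFactors <- function(counts) {
    counts <- as.matrix(counts)
    if (ncol(counts) < 2L)
        stop("TMM needs at least two libraries")
    totals <- colSums(counts)
    if (any(totals == 0)) {
        bad <- colnames(counts)[totals == 0]
        if (is.null(bad)) bad <- which(totals == 0)
        stop("library with all-zero counts: ", paste(bad, collapse = ", "))
    }
    f <- edgeR::calcNormFactors(counts, method = "TMM")
    names(f) <- colnames(counts)
    f
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of raw p-values.
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
bhAdjust <- function(p) p.adjust(p, method = "BH")

#' Negative-binomial likelihood-ratio test between two groups
#'
#' Fits, per gene, a negative-binomial GLM with TMM-scaled library-size
#' offsets and a single common dispersion estimated by adjusted profile
#' likelihood over all genes, and tests the group coefficient by a
#' likelihood-ratio test against \eqn{\chi^2(1)}. The log2 fold-change is
#' taken from the fitted group means (group A over group B). Genes with
#' zero counts in every library are flagged, assigned p = 1 and
#' log2FC = 0, and excluded from the BH denominator.
#'
#' @param counts genes x libraries raw count matrix.
#' @param group factor or vector with exactly two levels; the *second*
#'   level (or `groupA`) is the numerator of the fold-change.
#' @param groupA,groupB optional explicit level names (A = numerator).
#' @param normFactors optional TMM factors; computed when `NULL`.
#' @param dispSubset size of the systematic gene subset used for the
#'   common-dispersion estimate (all genes when the matrix is smaller).
#' @return A [DEResult-class] with columns `log2FC`, `pvalue`, `padj`,
#'   `fracA`, `fracB`, `meanA`, `meanB`, `allZero`.
#' @export
nbLRT <- function(counts, group, groupA = NULL, groupB = NULL,
                  normFactors = NULL, dispSubset = 1000L) {
    counts <- as.matrix(counts)
    group <- as.character(group)
    lv <- unique(group)
    if (length(lv) != 2L)
        stop("exactly two groups are required")
    if (is.null(groupA)) groupA <- lv[2L]
    if (is.null(groupB)) groupB <- setdiff(lv, groupA)
    if (!all(c(groupA, groupB) %in% lv))
        stop("groupA/groupB not found in the group labels")
    if (min(table(group)) < 2L)
        stop("each group needs at least two libraries (cells or replicates)")
    ## B first so the second coefficient is A-over-B
    fgroup <- factor(group, levels = c(groupB, groupA))
    if (is.null(normFactors)) normFactors <- tmmFactors(counts)

    allZero <- rowSums(counts) == 0
    kept <- counts[!allZero, , drop = FALSE]
    y <- edgeR::DGEList(counts = kept, group = fgroup,
                        norm.factors = normFactors)
    design <- model.matrix(~fgroup)
    y <- edgeR::estimateGLMCommonDisp(y, design, subset = dispSubset)
    fit <- edgeR::glmFit(y, design)
    lrt <- edgeR::glmLRT(fit, coef = 2L)
    tab <- lrt$table

    isA <- fgroup == groupA
    fracA <- rowMeans(counts[, isA, drop = FALSE] > 0)
    fracB <- rowMeans(counts[, !isA, drop = FALSE] > 0)
    cpms <- edgeR::cpm(edgeR::DGEList(counts = counts, group = fgroup,
                                      norm.factors = normFactors))
    meanA <- rowMeans(cpms[, isA, drop = FALSE])
    meanB <- rowMeans(cpms[, !isA, drop = FALSE])

    log2FC <- numeric(nrow(counts)); pvalue <- rep(1, nrow(counts))
    log2FC[!allZero] <- tab$logFC
    pvalue[!allZero] <- tab$PValue
    padj <- rep(1, nrow(counts))
    padj[!allZero] <- bhAdjust(tab$PValue)

    res <- new("DEResult",
               S4Vectors::DataFrame(
                   log2FC = log2FC, pvalue = pvalue, padj = padj,
                   fracA = fracA, fracB = fracB,
                   meanA = meanA, meanB = meanB, allZero = allZero,
                   row.names = rownames(counts)),
               groupA = groupA, groupB = groupB)
    res
}

#' Differential expression between two cell groups of an experiment
#'
#' Dispatcher assembling TMM factors, the NB likelihood-ratio test, BH
#' correction and per-group expression fractions for one contrast. Raw
#' counts feed the NB model; every cell is one library.
#'
#' @param sce a `SingleCellExperiment` (raw `counts` assay) or a genes x
#'   cells count matrix.
#' @param labels vector of group labels per cell (for an SCE, a `colData`
#'   column name is also accepted).
#' @param groupA,groupB the two labels to contrast (A = numerator). Cells
#'   with other labels are ignored. `groupB` may be `"rest"` to pool all
#'   remaining cells.
#' @return A [DEResult-class].
#' @export
deBetween <- function(sce, labels, groupA, groupB = "rest") {
    if (is(sce, "SummarizedExperiment")) {
        if (length(labels) == 1L && is.character(labels))
            labels <- colData(sce)[[labels]]
        mat <- as.matrix(counts(sce))
    } else mat <- as.matrix(sce)
    labels <- as.character(labels)
    stopifnot(length(labels) == ncol(mat))
    if (identical(groupB, "rest")) {
        sel <- rep(TRUE, length(labels))
        grp <- ifelse(labels == groupA, groupA, "rest")
    } else {
        sel <- labels %in% c(groupA, groupB)
        grp <- labels[sel]
    }
    if (sum(grp == groupA) < 2L || sum(grp != groupA) < 2L)
        stop("each group needs at least two cells")
    nbLRT(mat[, sel, drop = FALSE], grp, groupA = groupA,
          groupB = if (identical(groupB, "rest")) "rest" else groupB)
}
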
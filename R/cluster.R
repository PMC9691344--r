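#' @importFrom stats prcomp dist hclust cutree setNames
NULL

#' PCA embedding of cells
#'
#' Projects cells onto the leading principal components of the
#' gene-centered expression matrix (genes centered, not scaled), i.e. the
#' top right-singular directions of the centered matrix.
#'
#' @param mat genes x cells matrix of log-normalized values, typically
#'   restricted to the variable genes.
#' @param nPC number of components (30 by default).
#' @return cells x `nPC` coordinate matrix with an `"explainedVariance"`
#'   attribute (non-increasing).
#' @export
pcaEmbed <- function(mat, nPC = 30L) {
    mat <- as.matrix(mat)
    if (ncol(mat) < nPC + 1L)
        stop("need at least nPC + 1 cells for a ", nPC, "-component embedding")
    pc <- prcomp(t(mat), center = TRUE, scale. = FALSE, rank. = nPC)
    coords <- pc$x
    attr(coords, "explainedVariance") <- pc$sdev[seq_len(ncol(coords))]^2
    coords
}

#' t-SNE embedding (visualization plumbing)
#'
#' Two-dimensional t-SNE layout of the PCA coordinates (perplexity 30 by
#' default). When there are too few cells for the requested perplexity
#' (fewer than `3 * perplexity + 1`), the perplexity is reduced with a
#' warning. Deterministic under a fixed seed.
#'
#' @param pcs cells x components matrix from [pcaEmbed()].
#' @param perplexity t-SNE perplexity.
#' @param seed integer seed.
#' @param ... passed to `Rtsne::Rtsne`.
#' @return cells x 2 coordinate matrix.
#' @export
tsneEmbed <- function(pcs, perplexity = 30, seed = 1L, ...) {
    if (!requireNamespace("Rtsne", quietly = TRUE))
        stop("tsneEmbed requires the Rtsne package")
    n <- nrow(pcs)
    maxPerp <- floor((n - 1) / 3)
    if (perplexity > maxPerp) {
        warning("perplexity reduced from ", perplexity, " to ", maxPerp,
                " for ", n, " cells")
        perplexity <- maxPerp
    }
    set.seed(as.integer(seed))
    fit <- Rtsne::Rtsne(as.matrix(pcs), dims = 2, perplexity = perplexity,
                        pca = FALSE, check_duplicates = FALSE, ...)
    out <- fit$Y
    rownames(out) <- rownames(pcs)
    out
}

#' Ward hierarchical clustering into nested main/sub populations
#'
#' Computes Euclidean distances between log-normalized transcriptomes
#' (over the same variable-gene space as the projection), builds a Ward
#' dendrogram, and cuts it at `kMain` (2: main populations) and `kSub`
#' (4: subpopulations). Cuts of one dendrogram are nested, so every
#' subpopulation lies inside a single main population.
#'
#' @param mat genes x cells matrix of log-normalized values restricted to
#'   the variable genes.
#' @param kMain,kSub numbers of clusters at the two cut levels.
#' @return A [ClusterTree-class] object.
#' @export
wardCluster <- function(mat, kMain = 2L, kSub = 4L) {
    mat <- as.matrix(mat)
    if (ncol(mat) < kSub)
        stop("need at least ", kSub, " cells for the k=", kSub, " cut")
    hc <- hclust(dist(t(mat), method = "euclidean"), method = "ward.D2")
    new("ClusterTree",
        hclust = hc,
        mainLabels = cutree(hc, k = kMain),
        subLabels = cutree(hc, k = kSub),
        kMain = as.integer(kMain),
        kSub = as.integer(kSub))
}

#' Attach cluster labels to a SingleCellExperiment
#'
#' @param sce the experiment whose cells were clustered.
#' @param tree a [ClusterTree-class] from [wardCluster()].
#' @return `sce` with `colData` columns `mainCluster` and `subCluster`.
#' @export
addClusterLabels <- function(sce, tree) {
    stopifnot(is(tree, "ClusterTree"),
              length(mainClusters(tree)) == ncol(sce))
    colData(sce)$mainCluster <- factor(mainClusters(tree))
    colData(sce)$subCluster <- factor(subClusters(tree))
    sce
}
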
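#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assays colData colData<- rowData
#' @importClassesFrom S4Vectors DFrame
NULL

#' Simulation configuration for synthetic CAF datasets
#'
#' Parameters of the negative-binomial count simulator that emulates a
#' droplet-based single-cell experiment over several tumor samples with a
#' nested (2 main, 2x2 sub) CAF population structure and planted marker
#' genes. Counts are drawn as \eqn{NB(\mu, \alpha)} with
#' \eqn{Var = \mu + \alpha\mu^2}; gene means are relative baseline
#' abundances scaled by a per-cell log-normal library-size factor, and
#' marker fold-changes multiply the mean before library-size scaling so
#' that the planted fold-change is recoverable on the DE engine's scale.
#'
#' @slot nGenes number of genes.
#' @slot nCellsPerSample cells simulated per sample.
#' @slot nSamples number of samples (tumors).
#' @slot populationTree named list mapping each main population to the
#'   character vector of its subpopulations.
#' @slot markerPlan `data.frame` with columns `gene`, `population`,
#'   `foldChange` (>= 1); `population` may be a main or a sub label.
#' @slot libsizeLognormal numeric(2), mean-log and sd-log of the per-cell
#'   library-size factor.
#' @slot targetDepth expected total UMI count of an average cell.
#' @slot nbDispersion NB dispersion \eqn{\alpha} (> 0).
#' @slot seed integer seed; the same configuration and seed give
#'   bit-identical output.
#'
#' @seealso [simConfig()], [simulateCAFDataset()]
#' @export
setClass("SimConfig", representation(
    nGenes = "integer",
    nCellsPerSample = "integer",
    nSamples = "integer",
    populationTree = "list",
    markerPlan = "data.frame",
    libsizeLognormal = "numeric",
    targetDepth = "numeric",
    nbDispersion = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
    if (object@nCellsPerSample < 1L) msg <- c(msg, "nCellsPerSample must be >= 1")
    if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
    if (length(object@populationTree) < 1L ||
        is.null(names(object@populationTree)))
        msg <- c(msg, "populationTree must be a named list (main -> subs)")
    if (object@nbDispersion <= 0)
        msg <- c(msg, "nbDispersion must be positive")
    if (length(object@libsizeLognormal) != 2L)
        msg <- c(msg, "libsizeLognormal must be numeric(2) (meanlog, sdlog)")
    mp <- object@markerPlan
    if (nrow(mp) > 0L) {
        need <- c("gene", "population", "foldChange")
        if (!all(need %in% colnames(mp))) {
            msg <- c(msg, "markerPlan needs columns gene, population, foldChange")
        } else {
            if (any(mp$foldChange < 1))
                msg <- c(msg, "planted marker foldChange must be >= 1")
            pops <- c(names(object@populationTree),
                      unlist(object@populationTree, use.names = FALSE))
            if (!all(mp$population %in% pops))
                msg <- c(msg, "markerPlan population absent from populationTree")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig Constructor with the study's default conditions:
#'   2,000 genes, 6 samples of 300 cells, the 2-main/4-sub CAF tree, and 30
#'   planted markers per subpopulation at fold-change 8.
#'
#' @param nGenes,nCellsPerSample,nSamples,populationTree,markerPlan,
#'   libsizeLognormal,targetDepth,nbDispersion,seed see the class slots.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1L)
#' cfg
#' @export
simConfig <- function(nGenes = 2000L,
                      nCellsPerSample = 300L,
                      nSamples = 6L,
                      populationTree = list(
                          ECM = c("CP", "CS"),
                          Ctr = c("CtrI", "CtrII")),
                      markerPlan = NULL,
                      libsizeLognormal = c(0, 0.25),
                      targetDepth = 6000,
                      nbDispersion = 0.3,
                      seed = 1L) {
    if (is.null(markerPlan))
        markerPlan <- defaultMarkerPlan(nGenes, populationTree)
    if (nbDispersion <= 0)
        stop("nbDispersion must be positive")
    if (nrow(markerPlan) > 0L) {
        if (any(markerPlan$foldChange < 1))
            stop("planted marker foldChange must be >= 1")
        pops <- c(names(populationTree),
                  unlist(populationTree, use.names = FALSE))
        if (!all(markerPlan$population %in% pops))
            stop("markerPlan population absent from populationTree")
    }
    new("SimConfig",
        nGenes = as.integer(nGenes),
        nCellsPerSample = as.integer(nCellsPerSample),
        nSamples = as.integer(nSamples),
        populationTree = populationTree,
        markerPlan = markerPlan,
        libsizeLognormal = as.numeric(libsizeLognormal),
        targetDepth = as.numeric(targetDepth),
        nbDispersion = as.numeric(nbDispersion),
        seed = as.integer(seed))
}

#' Default marker plan: 30 markers per subpopulation at fold-change 8
#'
#' Assigns disjoint blocks of genes from the head of the gene list as
#' markers of each subpopulation (and, for nested trees, 30 markers per
#' main population shared by its subpopulations through the main label).
#'
#' @param nGenes number of genes in the simulated universe.
#' @param populationTree named list as in [SimConfig-class].
#' @param nPerPop markers per population.
#' @param foldChange planted fold-change (>= 1).
#' @return `data.frame(gene, population, foldChange)`.
#' @export
defaultMarkerPlan <- function(nGenes, populationTree,
                              nPerPop = 30L, foldChange = 8) {
    pops <- c(unlist(populationTree, use.names = FALSE),
              names(populationTree))
    if (length(populationTree) == 1L && is.null(populationTree[[1L]]))
        pops <- names(populationTree)
    nNeed <- nPerPop * length(pops)
    if (nNeed > nGenes)
        stop("not enough genes for the requested marker plan")
    data.frame(
        gene = sprintf("G%04d", seq_len(nNeed)),
        population = rep(pops, each = nPerPop),
        foldChange = foldChange,
        stringsAsFactors = FALSE)
}

#' @export
setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes x",
        object@nCellsPerSample, "cells x", object@nSamples, "samples\n")
    cat("  populations:",
        paste(vapply(names(object@populationTree), function(m)
            paste0(m, "(", paste(object@populationTree[[m]], collapse = ","), ")"),
            character(1)), collapse = " "), "\n")
    cat("  planted markers:", nrow(object@markerPlan),
        "| dispersion:", object@nbDispersion,
        "| seed:", object@seed, "\n")
})

#' Consensus marker gene signature
#'
#' An ordered marker gene list for one cluster, derived by the consensus
#' rules (expression-fraction, fold-change and adjusted-p gates against the
#' pooled complement and against every sibling cluster), capped at the top
#' K genes sorted by the ranking fold-change.
#'
#' @slot cluster cluster label the signature marks.
#' @slot rule one of `"sub"`, `"main"`, `"atlas"`.
#' @slot genes ordered character vector (ranking fold-change, descending).
#' @slot stats `DFrame` with one row per signature gene: `log2FC`
#'   (ranking contrast), `padj` (ranking contrast), `frac` (expression
#'   fraction in the cluster), plus the per-gate minima `minPairFC` and
#'   `maxPairPadj` across sibling contrasts.
#' @export
setClass("GeneSignature", representation(
    cluster = "character",
    rule = "character",
    genes = "character",
    stats = "DFrame"
))

setValidity("GeneSignature", function(object) {
    msg <- character()
    K <- switch(object@rule, atlas = 16L, 30L)
    if (length(object@genes) > K)
        msg <- c(msg, sprintf("signature longer than K=%d for rule '%s'",
                              K, object@rule))
    if (!object@rule %in% c("sub", "main", "atlas"))
        msg <- c(msg, "rule must be sub, main or atlas")
    if (nrow(object@stats) != length(object@genes))
        msg <- c(msg, "stats rows must match genes")
    if (length(object@genes) > 1L &&
        is.unsorted(rev(object@stats$log2FC), strictly = FALSE))
        msg <- c(msg, "genes must be sorted by ranking FC, descending")
    if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "GeneSignature", function(object) {
    cat(sprintf("GeneSignature '%s' (%s rule): %d genes\n",
                object@cluster, object@rule, length(object@genes)))
    if (length(object@genes))
        cat("  top:", paste(utils::head(object@genes, 8L), collapse = ", "),
            if (length(object@genes) > 8L) "..." else "", "\n")
})

#' @describeIn GeneSignature The ordered marker genes.
#' @param x,object a `GeneSignature`.
#' @export
signatureGenes <- function(x) x@genes

#' @describeIn GeneSignature The cluster the signature marks.
#' @export
signatureCluster <- function(x) x@cluster

#' @describeIn GeneSignature Per-gene selection statistics.
#' @export
signatureStats <- function(x) x@stats

#' @describeIn GeneSignature Number of signature genes.
#' @export
setMethod("length", "GeneSignature", function(x) length(x@genes))

#' Differential expression result
#'
#' One two-group contrast (group A over group B): per-gene log2 fold-change
#' on TMM-offset negative-binomial fitted means, raw and BH-adjusted
#' likelihood-ratio p-values, and the fraction of libraries (cells or
#' replicates) with a positive count in each group. Genes that are zero in
#' every library are flagged (`allZero`), assigned p = 1 and log2FC = 0,
#' and excluded from the BH denominator.
#'
#' @export
setClass("DEResult", contains = "DFrame",
         representation(groupA = "character", groupB = "character"))

#' @export
setMethod("show", "DEResult", function(object) {
    cat(sprintf("DEResult: %s vs %s, %d genes (%d all-zero)\n",
                object@groupA, object@groupB, nrow(object),
                sum(object$allZero)))
    cat(sprintf("  %d genes at padj <= 0.01 & |log2FC| >= 1\n",
                sum(!object$allZero & object$padj <= 0.01 &
                    abs(object$log2FC) >= 1, na.rm = TRUE)))
})

#' Fitted reference-origin classifier
#'
#' A classifier trained on a labeled reference atlas of liver mesenchymal
#' populations, used to assign a closest reference phenotype to each CAF.
#' Engines: `"randomForest"` (package randomForest, default parameters),
#' `"knn"` (k-nearest neighbors, Euclidean on log-normalized values,
#' k = 100, no per-feature normalization, majority vote with ties broken
#' toward the smallest class index), `"svmLinear"` (linear SVM on centered
#' and scaled features, cost tuned by repeated internal cross-validation).
#'
#' @slot engine engine name.
#' @slot features feature genes, identical at training and prediction.
#' @slot classes reference class labels fixed at fit time.
#' @slot fit fitted state (engine-specific).
#' @slot center,scale per-feature standardization used by the SVM engine
#'   (empty for other engines).
#' @export
setClass("OriginModel", representation(
    engine = "character",
    features = "character",
    classes = "character",
    fit = "ANY",
    center = "numeric",
    scale = "numeric"
))

#' @export
setMethod("show", "OriginModel", function(object) {
    cat(sprintf("OriginModel [%s]: %d features, classes: %s\n",
                object@engine, length(object@features),
                paste(object@classes, collapse = ", ")))
})

#' Ward cluster tree with nested main/sub cuts
#'
#' Agglomerative Ward linkage over Euclidean distances between
#' log-normalized transcriptomes (on the variable-gene space), with the
#' dendrogram cut at k = 2 (main populations) and k = 4 (subpopulations).
#' Cuts of a single dendrogram are nested by construction: each
#' subpopulation lies wholly inside one main population.
#'
#' @slot hclust the `stats::hclust` object (Ward linkage).
#' @slot mainLabels,subLabels named integer vectors of cluster memberships
#'   per cell at the two cut levels.
#' @slot kMain,kSub numbers of clusters at the two levels.
#' @export
setClass("ClusterTree", representation(
    hclust = "ANY",
    mainLabels = "integer",
    subLabels = "integer",
    kMain = "integer",
    kSub = "integer"
))

setValidity("ClusterTree", function(object) {
    msg <- character()
    if (length(object@mainLabels) != length(object@subLabels))
        msg <- c(msg, "main and sub labels must cover the same cells")
    ## each sub cluster must sit inside exactly one main cluster
    if (length(object@subLabels)) {
        split_main <- split(object@mainLabels, object@subLabels)
        if (any(vapply(split_main, function(v) length(unique(v)), 1L) != 1L))
            msg <- c(msg, "sub clusters must nest within main clusters")
    }
    h <- object@hclust$height
    if (length(h) > 1L && is.unsorted(h, strictly = FALSE) &&
        any(diff(h) < -1e-8 * max(abs(h), 1)))
        msg <- c(msg, "merge heights must be non-decreasing")
    if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "ClusterTree", function(object) {
    cat(sprintf("ClusterTree: %d cells, k=%d main / k=%d sub clusters\n",
                length(object@mainLabels), object@kMain, object@kSub))
    print(table(main = object@mainLabels, sub = object@subLabels))
})

#' @describeIn ClusterTree Main-level (k = 2) cluster labels.
#' @param x a `ClusterTree`.
#' @export
mainClusters <- function(x) x@mainLabels

#' @describeIn ClusterTree Sub-level (k = 4) cluster labels.
#' @export
subClusters <- function(x) x@subLabels
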
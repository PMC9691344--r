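## Consensus marker-signature derivation.
##
## All rules share the same gate structure: a gene enters a cluster's
## signature only if it is sufficiently detected in that cluster and is
## up-regulated (FC and adjusted-p gates) both against the pooled
## complement and against every sibling cluster individually; the
## surviving genes are ranked by the ranking fold-change and capped at K.

.mkSignature <- function(cluster, rule, keep, rankFC, padj, frac,
                         minPairFC, maxPairPadj, K) {
    genes <- names(keep)[keep]
    ord <- order(-rankFC[genes], genes)
    genes <- utils::head(genes[ord], K)
    new("GeneSignature",
        cluster = cluster, rule = rule, genes = genes,
        stats = S4Vectors::DataFrame(
            log2FC = unname(rankFC[genes]),
            padj = unname(padj[genes]),
            frac = unname(frac[genes]),
            minPairFC = unname(minPairFC[genes]),
            maxPairPadj = unname(maxPairPadj[genes]),
            row.names = genes))
}

#' Independent validator of signature gates
#'
#' Re-checks, from the stored per-gene statistics, that every emitted gene
#' satisfies every selection gate. Called by the signature constructors on
#' each run; exported so external code can audit a signature.
#'
#' @param sig a [GeneSignature-class].
#' @param fcMin,padjMax,minFrac the gate thresholds used at construction.
#' @return `TRUE` invisibly; stops otherwise.
#' @export
validateSignatureGates <- function(sig, fcMin = 2, padjMax = 0.01,
                                   minFrac = 0.2) {
    st <- signatureStats(sig)
    if (nrow(st) == 0L) return(invisible(TRUE))
    ok <- 2^st$log2FC >= fcMin & st$padj <= padjMax & st$frac >= minFrac &
        st$minPairFC >= fcMin & st$maxPairPadj <= padjMax
    if (!all(ok))
        stop("signature '", signatureCluster(sig),
             "' contains genes violating a selection gate")
    invisible(TRUE)
}

#' Consensus signature of one subcluster (or atlas cluster)
#'
#' A gene is kept iff it is expressed in at least `minFrac` of the
#' cluster's cells, and shows FC >= `fcMin` with adjusted p <= `padjMax`
#' versus the other clusters pooled together *and* versus each other
#' cluster individually. The top `K` surviving genes, sorted by the pooled
#' fold-change (descending), form the signature.
#'
#' @param cluster label of the cluster the signature marks.
#' @param dePooled [DEResult-class] of the cluster versus the pooled
#'   complement (cluster as group A).
#' @param deEach named list of [DEResult-class], one per sibling cluster
#'   (cluster as group A in each).
#' @param K signature cap (30 for CAF subclusters, 16 for atlas clusters).
#' @param fcMin,padjMax,minFrac gate thresholds.
#' @param rule stored rule tag (`"sub"` or `"atlas"`).
#' @return A [GeneSignature-class].
#' @export
subclusterSignature <- function(cluster, dePooled, deEach, K = 30L,
                                fcMin = 2, padjMax = 0.01, minFrac = 0.2,
                                rule = "sub") {
    stopifnot(is(dePooled, "DEResult"), length(deEach) >= 1L)
    genes <- rownames(dePooled)
    for (d in deEach)
        if (!identical(rownames(d), genes))
            stop("pairwise contrasts must cover the same genes")
    frac <- setNames(dePooled$fracA, genes)
    pooledFC <- setNames(dePooled$log2FC, genes)
    pooledP <- setNames(dePooled$padj, genes)
    pairFC <- do.call(cbind, lapply(deEach, function(d) d$log2FC))
    pairP <- do.call(cbind, lapply(deEach, function(d) d$padj))
    minPairFC <- setNames(2^apply(pairFC, 1L, min), genes)
    maxPairPadj <- setNames(apply(pairP, 1L, max), genes)
    keep <- frac >= minFrac &
        2^pooledFC >= fcMin & pooledP <= padjMax &
        minPairFC >= fcMin & maxPairPadj <= padjMax
    sig <- .mkSignature(cluster, rule, keep, pooledFC, pooledP, frac,
                        minPairFC, maxPairPadj, K)
    validateSignatureGates(sig, fcMin, padjMax, minFrac)
    sig
}

#' Consensus signature of a main cluster
#'
#' A gene is kept iff it is expressed in at least `minFrac` (20\%) of the
#' main cluster's cells and in at least `minFracSub` (10\%) of each of its
#' own subclusters, and shows FC >= `fcMin` with adjusted p <= `padjMax`
#' versus the other main cluster *and* versus each subcluster of the other
#' main cluster. Ranked by the fold-change versus the other main cluster;
#' top `K` kept.
#'
#' @param cluster main cluster label.
#' @param deMain [DEResult-class] versus the other main cluster (this
#'   cluster as group A).
#' @param deVsOtherSubs named list of [DEResult-class] versus each
#'   subcluster of the other main cluster.
#' @param fracOwnSubs named list (one per own subcluster) of per-gene
#'   detection fractions inside that subcluster, aligned to the DE genes.
#' @param K,fcMin,padjMax,minFrac,minFracSub thresholds.
#' @return A [GeneSignature-class] with rule `"main"`.
#' @export
mainSignature <- function(cluster, deMain, deVsOtherSubs, fracOwnSubs,
                          K = 30L, fcMin = 2, padjMax = 0.01,
                          minFrac = 0.2, minFracSub = 0.1) {
    stopifnot(is(deMain, "DEResult"),
              length(deVsOtherSubs) >= 1L, length(fracOwnSubs) >= 1L)
    genes <- rownames(deMain)
    frac <- setNames(deMain$fracA, genes)
    rankFC <- setNames(deMain$log2FC, genes)
    rankP <- setNames(deMain$padj, genes)
    subFracOK <- Reduce(`&`, lapply(fracOwnSubs, function(f)
        setNames(f, genes) >= minFracSub))
    pairFC <- do.call(cbind, lapply(deVsOtherSubs, function(d) d$log2FC))
    pairP <- do.call(cbind, lapply(deVsOtherSubs, function(d) d$padj))
    minPairFC <- setNames(2^apply(pairFC, 1L, min), genes)
    maxPairPadj <- setNames(apply(pairP, 1L, max), genes)
    keep <- frac >= minFrac & subFracOK &
        2^rankFC >= fcMin & rankP <= padjMax &
        minPairFC >= fcMin & maxPairPadj <= padjMax
    sig <- .mkSignature(cluster, "main", keep, rankFC, rankP, frac,
                        minPairFC, maxPairPadj, K)
    validateSignatureGates(sig, fcMin, padjMax, minFrac)
    sig
}

#' @describeIn subclusterSignature Atlas variant: same gate structure over
#'   three flat clusters, capped at the top 16 genes.
#' @export
atlasSignature <- function(cluster, dePooled, deEach, K = 16L,
                           fcMin = 2, padjMax = 0.01, minFrac = 0.2) {
    subclusterSignature(cluster, dePooled, deEach, K = K, fcMin = fcMin,
                        padjMax = padjMax, minFrac = minFrac,
                        rule = "atlas")
}

#' Per-gene detection fraction within a cell subset
#'
#' @param sce `SingleCellExperiment` or count matrix.
#' @param cells logical or index vector selecting the subset.
#' @return Per-gene fraction of selected cells with count > 0.
#' @export
expressionFraction <- function(sce, cells) {
    mat <- if (is(sce, "SummarizedExperiment")) counts(sce) else sce
    Matrix::rowMeans(mat[, cells, drop = FALSE] > 0)
}

#' Derive all nested CAF signatures from a clustered experiment
#'
#' Runs every required contrast (each subcluster versus the pooled rest
#' and versus each sibling; each main cluster versus the other and versus
#' the other's subclusters) and applies the consensus rules.
#'
#' @param sce a `SingleCellExperiment` with raw counts and cluster labels.
#' @param subCol,mainCol `colData` columns holding sub and main cluster
#'   labels.
#' @param K signature cap.
#' @return list with `sub` and `main`: named lists of
#'   [GeneSignature-class] objects, plus `contrasts` (the DEResults).
#' @export
deriveSignatures <- function(sce, subCol = "subCluster",
                             mainCol = "mainCluster", K = 30L) {
    subLab <- as.character(colData(sce)[[subCol]])
    mainLab <- as.character(colData(sce)[[mainCol]])
    subs <- sort(unique(subLab))
    mains <- sort(unique(mainLab))
    stopifnot(length(mains) == 2L)
    mainOf <- vapply(subs, function(s)
        unique(mainLab[subLab == s]), character(1))
    mat <- as.matrix(counts(sce))

    ## pooled and pairwise subcluster contrasts
    pooled <- lapply(subs, function(s) deBetween(mat, subLab, s, "rest"))
    names(pooled) <- subs
    pair <- list()
    for (i in seq_along(subs)) for (j in seq_along(subs)) if (i < j) {
        d <- deBetween(mat, subLab, subs[i], subs[j])
        pair[[paste(subs[i], subs[j], sep = "|")]] <- d
    }
    getPair <- function(a, b) {
        key <- paste(sort(c(a, b))[1], sort(c(a, b))[2], sep = "|")
        d <- pair[[key]]
        if (d@groupA == a) return(d)
        flipDEResult(d)
    }
    sigSub <- lapply(subs, function(s) {
        others <- setdiff(subs, s)
        deEach <- lapply(others, function(o) getPair(s, o))
        names(deEach) <- others
        subclusterSignature(s, pooled[[s]], deEach, K = K)
    })
    names(sigSub) <- subs

    ## main contrasts
    deMainAB <- deBetween(mat, mainLab, mains[1], mains[2])
    deMainList <- list(deMainAB, flipDEResult(deMainAB))
    names(deMainList) <- mains
    sigMain <- lapply(mains, function(m) {
        other <- setdiff(mains, m)
        otherSubs <- subs[mainOf == other]
        ownSubs <- subs[mainOf == m]
        deVsOtherSubs <- lapply(otherSubs, function(t) {
            ## disambiguate: a recovered sub label may equal a main label
            lab <- ifelse(subLab == t, paste0("sub.", t),
                          ifelse(mainLab == m, paste0("main.", m), NA))
            d <- deBetween(mat, lab, paste0("main.", m), paste0("sub.", t))
            d@groupA <- m; d@groupB <- t
            d
        })
        names(deVsOtherSubs) <- otherSubs
        fracOwnSubs <- lapply(ownSubs, function(s)
            expressionFraction(mat, subLab == s))
        names(fracOwnSubs) <- ownSubs
        mainSignature(m, deMainList[[m]], deVsOtherSubs, fracOwnSubs, K = K)
    })
    names(sigMain) <- mains
    list(sub = sigSub, main = sigMain,
         contrasts = list(pooled = pooled, pairwise = pair,
                          main = deMainList))
}

#' Derive atlas-cluster signatures (flat, top-16 rule)
#'
#' @param sce labeled reference `SingleCellExperiment`.
#' @param popCol `colData` column with the population labels.
#' @param K signature cap (16).
#' @return Named list of [GeneSignature-class] objects.
#' @export
deriveAtlasSignatures <- function(sce, popCol = "population", K = 16L) {
    lab <- as.character(colData(sce)[[popCol]])
    pops <- sort(unique(lab))
    mat <- as.matrix(counts(sce))
    pooled <- lapply(pops, function(p) deBetween(mat, lab, p, "rest"))
    names(pooled) <- pops
    pair <- list()
    for (i in seq_along(pops)) for (j in seq_along(pops)) if (i < j)
        pair[[paste(pops[i], pops[j], sep = "|")]] <-
            deBetween(mat, lab, pops[i], pops[j])
    getPair <- function(a, b) {
        key <- paste(sort(c(a, b))[1], sort(c(a, b))[2], sep = "|")
        d <- pair[[key]]
        if (d@groupA == a) d else flipDEResult(d)
    }
    sigs <- lapply(pops, function(p) {
        others <- setdiff(pops, p)
        deEach <- lapply(others, function(o) getPair(p, o))
        names(deEach) <- others
        atlasSignature(p, pooled[[p]], deEach, K = K)
    })
    names(sigs) <- pops
    sigs
}

#' Reverse the direction of a DE contrast
#'
#' Swaps groups A and B: fold-changes are negated, p-values and fractions
#' swap sides; the likelihood-ratio test itself is symmetric.
#'
#' @param de a [DEResult-class].
#' @return The flipped [DEResult-class].
#' @export
flipDEResult <- function(de) {
    new("DEResult",
        S4Vectors::DataFrame(
            log2FC = -de$log2FC, pvalue = de$pvalue, padj = de$padj,
            fracA = de$fracB, fracB = de$fracA,
            meanA = de$meanB, meanB = de$meanA, allZero = de$allZero,
            row.names = rownames(de)),
        groupA = de@groupB, groupB = de@groupA)
}

#' Hypergeometric signature-overlap test
#'
#' Upper-tail hypergeometric probability of observing at least the actual
#' overlap between two gene sets drawn from a common universe.
#'
#' @param sigA,sigB [GeneSignature-class] objects or character vectors.
#' @param universeSize size of the gene universe (by convention, the genes
#'   tested in both datasets).
#' @return list with `overlap` and `p`.
#' @export
signatureOverlapTest <- function(sigA, sigB, universeSize) {
    a <- if (is(sigA, "GeneSignature")) signatureGenes(sigA) else sigA
    b <- if (is(sigB, "GeneSignature")) signatureGenes(sigB) else sigB
    stopifnot(universeSize >= length(union(a, b)))
    k <- length(intersect(a, b))
    p <- phyper(k - 1L, length(a), universeSize - length(a), length(b),
                lower.tail = FALSE)
    list(overlap = k, p = p)
}

#' Mean signature expression per cell
#'
#' @param x `SingleCellExperiment` (uses `logcounts`) or a genes x cells
#'   matrix of log-normalized values.
#' @param sig [GeneSignature-class] or character vector of genes.
#' @return Named numeric vector of per-cell scores (mean log-normalized
#'   expression of the signature genes).
#' @export
scoreSignatureOnCells <- function(x, sig) {
    genes <- if (is(sig, "GeneSignature")) signatureGenes(sig) else sig
    if (length(genes) == 0L)
        stop("cannot score an empty signature")
    mat <- if (is(x, "SummarizedExperiment")) logcounts(x) else x
    missing <- setdiff(genes, rownames(mat))
    if (length(missing) == length(genes))
        stop("none of the signature genes are present in the matrix")
    if (length(missing))
        warning(length(missing), " signature gene(s) absent; scored on ",
                length(genes) - length(missing))
    genes <- setdiff(genes, missing)
    colMeans(as.matrix(mat[genes, , drop = FALSE]))
}

#' Export signatures as a GMT gene-set file
#'
#' @param sigs named list of [GeneSignature-class] objects (or character
#'   vectors).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSignatureGMT <- function(sigs, path) {
    lines <- vapply(names(sigs), function(nm) {
        genes <- if (is(sigs[[nm]], "GeneSignature"))
            signatureGenes(sigs[[nm]]) else sigs[[nm]]
        paste(c(nm, nm, genes), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}
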
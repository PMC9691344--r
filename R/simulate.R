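#' @importFrom stats rlnorm rnbinom median quantile rnorm sd var
#' @importFrom Matrix readMM writeMM colSums rowSums t sparseMatrix
#' @importFrom SingleCellExperiment SingleCellExperiment logcounts logcounts<- counts
NULL

## Draw a gene x cell NB count matrix from a mean matrix and a common
## dispersion alpha (Var = mu + alpha mu^2), i.e. size = 1/alpha.
.simNBMatrix <- function(mu, dispersion) {
    counts <- rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion)
    matrix(counts, nrow = nrow(mu), ncol = ncol(mu), dimnames = dimnames(mu))
}

## Relative baseline abundances, scaled so an average cell totals targetDepth.
.baselineMeans <- function(config, sdlog = 1) {
    w <- rlnorm(config@nGenes, meanlog = 0, sdlog = sdlog)
    m <- w / sum(w) * config@targetDepth
    names(m) <- sprintf("G%04d", seq_len(config@nGenes))
    m
}

## Per-population fold-change vector from a marker plan; a cell inherits
## boosts from both its sub label and its main label.
.fcVector <- function(geneNames, markerPlan, labels) {
    fc <- rep(1, length(geneNames))
    names(fc) <- geneNames
    sel <- markerPlan$population %in% labels
    if (any(sel)) {
        mp <- markerPlan[sel, , drop = FALSE]
        fc[mp$gene] <- fc[mp$gene] * mp$foldChange
    }
    fc
}

#' Simulate a multi-sample CAF single-cell dataset with planted truth
#'
#' Generates UMI counts for `nSamples` tumor samples, each containing all
#' four CAF subpopulations nested in two main populations, as
#' negative-binomial draws around gene baseline abundances multiplied by
#' planted marker fold-changes and a log-normal per-cell library-size
#' factor. All downstream stages of the pipeline can be validated against
#' the returned ground truth.
#'
#' @param config a [SimConfig-class] object.
#' @return A [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `counts` assay, `colData` columns `sample`, `mainPop`, `subPop`, and
#'   `metadata(sce)$truth` holding the marker table, population
#'   proportions and the configuration.
#' @examples
#' sce <- simulateCAFDataset(simConfig(nGenes = 200L, nCellsPerSample = 50L,
#'                                     nSamples = 2L, seed = 7L))
#' table(sce$subPop, sce$sample)
#' @export
simulateCAFDataset <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    base <- .baselineMeans(config)
    tree <- config@populationTree
    subs <- unlist(tree, use.names = FALSE)
    mainOf <- rep(names(tree), lengths(tree))
    names(mainOf) <- subs
    ## fixed subpopulation proportions per sample
    prop <- rep(1 / length(subs), length(subs))
    nSub <- diff(round(cumsum(c(0, prop)) * config@nCellsPerSample))

    blocks <- list(); meta <- list()
    for (s in seq_len(config@nSamples)) {
        lib <- rlnorm(config@nCellsPerSample,
                      config@libsizeLognormal[1], config@libsizeLognormal[2])
        off <- 0L
        for (i in seq_along(subs)) {
            n <- nSub[i]
            if (n == 0L) next
            fc <- .fcVector(names(base), config@markerPlan,
                            c(subs[i], mainOf[subs[i]]))
            mu <- outer(base * fc, lib[off + seq_len(n)])
            rownames(mu) <- names(base)
            colnames(mu) <- sprintf("S%d_C%04d", s, off + seq_len(n))
            blocks[[length(blocks) + 1L]] <- .simNBMatrix(mu, config@nbDispersion)
            meta[[length(meta) + 1L]] <- data.frame(
                barcode = colnames(mu),
                sample = sprintf("S%d", s),
                mainPop = unname(mainOf[subs[i]]),
                subPop = subs[i],
                stringsAsFactors = FALSE)
            off <- off + n
        }
    }
    countsMat <- do.call(cbind, blocks)
    cd <- do.call(rbind, meta)
    rownames(cd) <- cd$barcode
    sce <- SingleCellExperiment(
        assays = list(counts = methods::as(countsMat, "CsparseMatrix")),
        colData = S4Vectors::DataFrame(cd[, c("sample", "mainPop", "subPop")]))
    S4Vectors::metadata(sce)$truth <- list(
        markerTable = config@markerPlan,
        proportions = stats::setNames(prop, subs),
        config = config)
    sce
}

#' Simulate a labeled reference atlas of liver mesenchymal populations
#'
#' Generates a flat three-population reference (VSMC-like, HSC-like and
#' scar-associated mesenchyme-like cells) with its own planted markers.
#' When the marker table of a simulated CAF dataset is supplied, a
#' configurable fraction of each CAF subpopulation's markers is re-used as
#' markers of the corresponding atlas population (CP/CS -> SAMes,
#' CtrI -> VSMC, CtrII -> HSC), so that origin transfer is learnable.
#'
#' @param config a [SimConfig-class]; `nCellsPerSample` is the number of
#'   cells per atlas population and `nSamples` is ignored.
#' @param cafMarkers optional marker table (`gene`, `population`,
#'   `foldChange`) from [simulateCAFDataset()] truth.
#' @param sharedFraction fraction of each mapped CAF subpopulation's
#'   markers re-used by the atlas population (0 disables sharing, making
#'   origin transfer unlearnable).
#' @param originMap named character vector CAF subpopulation -> atlas
#'   population.
#' @param populations atlas population labels.
#' @return A `SingleCellExperiment` with `counts`, `colData$population`,
#'   and `metadata(sce)$truth` (atlas marker table and the origin map).
#' @export
simulateReferenceAtlas <- function(config,
                                   cafMarkers = NULL,
                                   sharedFraction = 0.5,
                                   originMap = c(CP = "SAMes", CS = "SAMes",
                                                 CtrI = "VSMC", CtrII = "HSC"),
                                   populations = c("VSMC", "HSC", "SAMes")) {
    stopifnot(is(config, "SimConfig"))
    stopifnot(sharedFraction >= 0, sharedFraction <= 1)
    set.seed(config@seed)
    base <- .baselineMeans(config)
    genes <- names(base)
    ## own markers: disjoint blocks from the tail of the gene list, clear of
    ## the default CAF marker block at the head
    nPer <- 30L
    own <- data.frame(
        gene = genes[config@nGenes - seq_len(nPer * length(populations)) + 1L],
        population = rep(populations, each = nPer),
        foldChange = 8,
        stringsAsFactors = FALSE)
    plan <- own
    if (!is.null(cafMarkers) && sharedFraction > 0) {
        shared <- lapply(names(originMap), function(sub) {
            mk <- cafMarkers[cafMarkers$population == sub, , drop = FALSE]
            mk <- mk[mk$gene %in% genes, , drop = FALSE]
            k <- floor(sharedFraction * nrow(mk))
            if (k == 0L) return(NULL)
            data.frame(gene = mk$gene[seq_len(k)],
                       population = originMap[[sub]],
                       foldChange = mk$foldChange[seq_len(k)],
                       stringsAsFactors = FALSE)
        })
        plan <- rbind(plan, do.call(rbind, shared))
    }
    n <- config@nCellsPerSample
    blocks <- list(); labels <- character()
    lib <- rlnorm(n * length(populations),
                  config@libsizeLognormal[1], config@libsizeLognormal[2])
    for (i in seq_along(populations)) {
        fc <- rep(1, length(base)); names(fc) <- genes
        mp <- plan[plan$population == populations[i], , drop = FALSE]
        fc[mp$gene] <- mp$foldChange
        mu <- outer(base * fc, lib[(i - 1L) * n + seq_len(n)])
        rownames(mu) <- genes
        colnames(mu) <- sprintf("%s_C%04d", populations[i], seq_len(n))
        blocks[[i]] <- .simNBMatrix(mu, config@nbDispersion)
        labels <- c(labels, rep(populations[i], n))
    }
    countsMat <- do.call(cbind, blocks)
    sce <- SingleCellExperiment(
        assays = list(counts = methods::as(countsMat, "CsparseMatrix")),
        colData = S4Vectors::DataFrame(population = labels,
                                       row.names = colnames(countsMat)))
    S4Vectors::metadata(sce)$truth <- list(markerTable = plan,
                                           originMap = originMap)
    sce
}

#' Plant a ligand-receptor interaction truth
#'
#' Builds a curated-style ligand-receptor pair table together with an
#' expression plan that boosts ligand expression in the designated source
#' CAF population (and receptor expression in cancer cells), such that
#' planted "biased" pairs exceed both the median-score reliability gate and
#' the bias gates (score difference and ligand differential expression),
#' while "reliable" pairs exceed only the reliability gate and "null" pairs
#' carry no planted signal.
#'
#' @param config a [SimConfig-class] (defines the gene universe).
#' @param nBiasedA,nBiasedB planted pairs biased toward the first (ECM) and
#'   second (Ctr) main CAF population.
#' @param nReliable planted reliable-but-unbiased pairs.
#' @param nNull pairs with no planted signal.
#' @param ligandFC fold-change of the ligand in its source population.
#' @return list with `pairs` (`ligand`, `receptor`, `class` in
#'   biased_ECM/biased_Ctr/reliable/null) and `plan` (gene, population,
#'   foldChange) consumed by [simulateInteractionDataset()].
#' @export
simulateLRTruth <- function(config, nBiasedA = 5L, nBiasedB = 5L,
                            nReliable = 10L, nNull = 40L, ligandFC = 8) {
    stopifnot(is(config, "SimConfig"))
    nPairs <- nBiasedA + nBiasedB + nReliable + nNull
    genes <- sprintf("G%04d", seq_len(config@nGenes))
    ## reserve a mid-range block, clear of CAF (head) and atlas (tail) markers
    start <- 400L
    if (start + 2L * nPairs - 1L > config@nGenes)
        stop("gene universe too small for the requested pair table")
    lig <- genes[start + seq_len(nPairs)]
    rec <- genes[start + nPairs + seq_len(nPairs)]
    cls <- c(rep("biased_ECM", nBiasedA), rep("biased_Ctr", nBiasedB),
             rep("reliable", nReliable), rep("null", nNull))
    pairs <- data.frame(ligand = lig, receptor = rec, class = cls,
                        stringsAsFactors = FALSE)
    plan <- list()
    add <- function(g, p, f) data.frame(gene = g, population = p,
                                        foldChange = f)
    for (i in seq_len(nPairs)) {
        pl <- switch(cls[i],
            biased_ECM = list(add(lig[i], "ECM", ligandFC),
                              add(rec[i], "Cancer", ligandFC)),
            biased_Ctr = list(add(lig[i], "Ctr", ligandFC),
                              add(rec[i], "Cancer", ligandFC)),
            reliable = list(add(lig[i], "ECM", ligandFC),
                            add(lig[i], "Ctr", ligandFC),
                            add(rec[i], "Cancer", ligandFC)),
            null = NULL)
        plan <- c(plan, pl)
    }
    list(pairs = pairs, plan = do.call(rbind, plan))
}

#' Simulate the CAF + cancer-cell dataset for interaction scoring
#'
#' Generates, for each of `nSamples` samples, cells of the two main CAF
#' populations (ECM, Ctr) and of the cancer-cell population, with the
#' ligand/receptor boosts of a planted interaction truth. Ligand and
#' receptor genes are anchored to a common low baseline abundance so that
#' the planted fold-changes translate into interaction-score differences
#' above the selection thresholds.
#'
#' @param config a [SimConfig-class]; `nCellsPerSample` is the number of
#'   cells per population per sample.
#' @param lrTruth result of [simulateLRTruth()].
#' @return A `SingleCellExperiment` with `counts`, `colData` columns
#'   `sample` and `population` (ECM/Ctr/Cancer), and the truth in
#'   `metadata(sce)$truth`.
#' @export
simulateInteractionDataset <- function(config, lrTruth) {
    stopifnot(is(config, "SimConfig"))
    set.seed(config@seed)
    base <- .baselineMeans(config)
    ## anchor LR genes to a low common baseline: boosted means stay in the
    ## informative range of the saturating interaction score
    lrGenes <- unique(c(lrTruth$pairs$ligand, lrTruth$pairs$receptor))
    base[lrGenes] <- unname(quantile(base, 0.15))
    pops <- c("ECM", "Ctr", "Cancer")
    n <- config@nCellsPerSample
    blocks <- list(); meta <- list()
    for (s in seq_len(config@nSamples)) {
        lib <- rlnorm(n * length(pops),
                      config@libsizeLognormal[1], config@libsizeLognormal[2])
        for (i in seq_along(pops)) {
            fc <- rep(1, length(base)); names(fc) <- names(base)
            mp <- lrTruth$plan
            if (!is.null(mp)) {
                mp <- mp[mp$population == pops[i], , drop = FALSE]
                fc[mp$gene] <- mp$foldChange
            }
            mu <- outer(base * fc, lib[(i - 1L) * n + seq_len(n)])
            rownames(mu) <- names(base)
            colnames(mu) <- sprintf("S%d_%s_C%04d", s, pops[i], seq_len(n))
            blocks[[length(blocks) + 1L]] <- .simNBMatrix(mu, config@nbDispersion)
            meta[[length(meta) + 1L]] <- data.frame(
                barcode = colnames(mu), sample = sprintf("S%d", s),
                population = pops[i], stringsAsFactors = FALSE)
        }
    }
    countsMat <- do.call(cbind, blocks)
    cd <- do.call(rbind, meta)
    rownames(cd) <- cd$barcode
    sce <- SingleCellExperiment(
        assays = list(counts = methods::as(countsMat, "CsparseMatrix")),
        colData = S4Vectors::DataFrame(cd[, c("sample", "population")]))
    S4Vectors::metadata(sce)$truth <- lrTruth
    sce
}

#' Simulate a two-condition bulk RNA-seq experiment with planted DE genes
#'
#' Emulates an siRNA-silencing experiment: negative-binomial counts for two
#' conditions with `nReps` replicates each, the first `nDE` genes planted
#' at `log2FC` (half up-, half down-regulated in the treated condition).
#'
#' @param nGenes,nDE number of genes and of planted DE genes.
#' @param log2FC absolute planted log2 fold-change.
#' @param nReps replicates per condition.
#' @param dispersion NB dispersion (bulk-scale, e.g. 0.05).
#' @param depth expected library size.
#' @param seed integer seed.
#' @return list with `counts` (genes x samples), `group` (factor,
#'   levels ctrl/treated) and `truth` (`gene`, `log2FC`).
#' @export
simulateBulkExperiment <- function(nGenes = 5000L, nDE = 100L, log2FC = 2,
                                   nReps = 4L, dispersion = 0.05,
                                   depth = 5e5, seed = 1L) {
    stopifnot(nDE <= nGenes, nReps >= 1L)
    set.seed(as.integer(seed))
    w <- rlnorm(nGenes, 0, 1)
    base <- w / sum(w) * depth
    genes <- sprintf("G%04d", seq_len(nGenes))
    lfc <- numeric(nGenes)
    if (nDE > 0L)
        lfc[seq_len(nDE)] <- rep(c(log2FC, -log2FC), length.out = nDE)
    lib <- rlnorm(2L * nReps, 0, 0.1)
    mu <- cbind(outer(base, lib[seq_len(nReps)]),
                outer(base * 2^lfc, lib[nReps + seq_len(nReps)]))
    dimnames(mu) <- list(genes,
                         c(sprintf("ctrl_%d", seq_len(nReps)),
                           sprintf("treated_%d", seq_len(nReps))))
    counts <- .simNBMatrix(mu, dispersion)
    list(counts = counts,
         group = factor(rep(c("ctrl", "treated"), each = nReps),
                        levels = c("ctrl", "treated")),
         truth = data.frame(gene = genes[lfc != 0],
                            log2FC = lfc[lfc != 0],
                            stringsAsFactors = FALSE))
}

#' Write / read a count matrix in the 10x MatrixMarket triplet dialect
#'
#' `write10xMTX` writes `matrix.mtx` (MatrixMarket coordinate, integer),
#' `features.tsv` (id, name, "Gene Expression"; no header) and
#' `barcodes.tsv`. `read10xMTX` reads the triplet back; the round trip is
#' exact.
#'
#' @param x a matrix or sparse Matrix of counts with dimnames.
#' @param dir directory to write to / read from (created if missing).
#' @return `write10xMTX` returns `dir` invisibly; `read10xMTX` returns a
#'   `dgCMatrix` with gene and barcode dimnames.
#' @examples
#' m <- Matrix::rsparsematrix(5, 4, 0.5)
#' m@x <- round(abs(m@x) * 10)
#' dimnames(m) <- list(paste0("G", 1:5), paste0("C", 1:4))
#' d <- file.path(tempdir(), "mtx_example")
#' write10xMTX(m, d)
#' identical(as.matrix(read10xMTX(d)), as.matrix(m))
#' @export
write10xMTX <- function(x, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    x <- methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
    if ((nrow(x) > 0L && is.null(rownames(x))) ||
        (ncol(x) > 0L && is.null(colnames(x))))
        stop("matrix must carry gene and barcode dimnames")
    Matrix::writeMM(x, file.path(dir, "matrix.mtx"))
    rn <- if (nrow(x)) rownames(x) else character()
    cn <- if (ncol(x)) colnames(x) else character()
    writeLines(if (length(rn)) paste(rn, rn, "Gene Expression", sep = "\t")
               else character(), file.path(dir, "features.tsv"))
    writeLines(cn, file.path(dir, "barcodes.tsv"))
    invisible(dir)
}

#' @rdname write10xMTX
#' @export
read10xMTX <- function(dir) {
    m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
    featLines <- readLines(file.path(dir, "features.tsv"))
    genes <- vapply(strsplit(featLines, "\t", fixed = TRUE), `[`, "", 1L)
    bc <- readLines(file.path(dir, "barcodes.tsv"))
    m <- methods::as(m, "CsparseMatrix")
    dimnames(m) <- list(if (nrow(m)) genes else NULL,
                        if (ncol(m)) bc else NULL)
    m
}
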
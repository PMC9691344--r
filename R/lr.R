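#' Regularized ligand-receptor interaction score
#'
#' \deqn{s = \frac{\sqrt{l r}}{\mu + \sqrt{l r}}}
#' where `l` is the mean ligand expression in the source population, `r`
#' the mean receptor expression in the target population (log-normalized
#' scale), and `mu` the mean of the whole expression matrix, acting as a
#' regularizer. The score lies in [0, 1), is monotone non-decreasing in
#' both `l` and `r`, equals 0 iff `l * r = 0`, and equals 0.5 exactly at
#' `l = r = mu`. A score above 0.5 marks a confident interaction.
#'
#' @param l,r non-negative mean expression values (vectorized).
#' @param mu positive regularizer.
#' @return Scores in [0, 1).
#' @examples
#' lrScore(1, 1, 1)      # 0.5
#' lrScore(4, 1, 1)      # 2/3
#' @export
lrScore <- function(l, r, mu) {
    stopifnot(all(l >= 0), all(r >= 0), all(mu > 0))
    s <- sqrt(l * r)
    s / (mu + s)
}

#' Score all ligand-receptor pairs between populations, per sample
#'
#' For each ordered (source, target) population pair and each
#' ligand-receptor pair, computes one score per sample from the mean
#' log-normalized ligand expression in the source population and receptor
#' expression in the target population of that sample; `mu` is the mean
#' of the log-normalized matrix over that sample's participating cells.
#' Samples in which either population has fewer than `minCells` cells are
#' skipped for that record. The median score over contributing samples
#' defines reliability (`median > 0.5`, strict).
#'
#' @param sce `SingleCellExperiment` with `logcounts`, and `colData`
#'   columns for sample and population.
#' @param pairs `data.frame` with columns `ligand` and `receptor`; rows
#'   whose genes are absent from the matrix are skipped (recorded in the
#'   `skippedPairs` attribute).
#' @param sampleCol,populationCol `colData` column names.
#' @param sources,targets populations to score as sources/targets
#'   (default: all, paracrine directions only unless `autocrine = TRUE`).
#' @param minCells minimum cells per population per sample.
#' @param muScope `"sample"` (mean over the sample's participating cells,
#'   default) or `"global"` (mean over the whole matrix).
#' @param autocrine score source == target directions too.
#' @return `data.frame` with one row per (pair, source, target):
#'   per-sample score columns, `median`, `nSamples`, `reliable`.
#' @export
scoreLRInteractions <- function(sce, pairs,
                                sampleCol = "sample",
                                populationCol = "population",
                                sources = NULL, targets = NULL,
                                minCells = 10L, muScope = "sample",
                                autocrine = FALSE) {
    stopifnot(all(c("ligand", "receptor") %in% colnames(pairs)))
    mat <- logcounts(sce)
    samp <- as.character(colData(sce)[[sampleCol]])
    pop <- as.character(colData(sce)[[populationCol]])
    pops <- unique(pop)
    if (is.null(sources)) sources <- pops
    if (is.null(targets)) targets <- pops
    samples <- unique(samp)

    present <- pairs$ligand %in% rownames(mat) &
        pairs$receptor %in% rownames(mat)
    skipped <- pairs[!present, , drop = FALSE]
    pairs <- pairs[present, , drop = FALSE]
    pairs <- pairs[!duplicated(pairs[, c("ligand", "receptor")]), ,
                   drop = FALSE]

    ## per sample x population mean expression of the genes involved
    genes <- unique(c(pairs$ligand, pairs$receptor))
    meanExpr <- list()   # [[sample]][[population]] named vector
    nCells <- list()
    muSample <- list()   # [[sample]][[source|target]] handled below
    for (s in samples) {
        meanExpr[[s]] <- list(); nCells[[s]] <- list()
        for (p in pops) {
            cells <- samp == s & pop == p
            nCells[[s]][[p]] <- sum(cells)
            if (sum(cells) > 0L)
                meanExpr[[s]][[p]] <-
                    Matrix::rowMeans(mat[genes, cells, drop = FALSE])
        }
    }
    matMean <- function(m) sum(m) / (as.numeric(nrow(m)) * ncol(m))
    muGlobal <- matMean(mat)
    muFor <- function(s, src, tgt) {
        if (muScope == "global") return(muGlobal)
        cells <- samp == s & pop %in% unique(c(src, tgt))
        matMean(mat[, cells, drop = FALSE])
    }

    out <- list()
    for (src in sources) for (tgt in targets) {
        if (src == tgt && !autocrine) next
        mus <- vapply(samples, function(s) {
            if (nCells[[s]][[src]] >= minCells &&
                nCells[[s]][[tgt]] >= minCells) muFor(s, src, tgt)
            else NA_real_
        }, numeric(1))
        for (i in seq_len(nrow(pairs))) {
            sc <- vapply(samples, function(s) {
                if (is.na(mus[[s]])) return(NA_real_)
                l <- meanExpr[[s]][[src]][[pairs$ligand[i]]]
                r <- meanExpr[[s]][[tgt]][[pairs$receptor[i]]]
                lrScore(l, r, mus[[s]])
            }, numeric(1))
            med <- median(sc, na.rm = TRUE)
            row <- data.frame(ligand = pairs$ligand[i],
                              receptor = pairs$receptor[i],
                              source = src, target = tgt,
                              stringsAsFactors = FALSE)
            row[paste0("score_", samples)] <- as.list(sc)
            row$median <- med
            row$nSamples <- sum(!is.na(sc))
            row$reliable <- !is.na(med) && med > 0.5
            out[[length(out) + 1L]] <- row
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "skippedPairs") <- skipped
    res
}

#' Count reliable interactions per directed population pair
#'
#' @param records result of [scoreLRInteractions()].
#' @return source x target matrix of counts of reliable records.
#' @export
countInteractions <- function(records) {
    srcs <- sort(unique(records$source))
    tgts <- sort(unique(records$target))
    m <- matrix(0L, length(srcs), length(tgts),
                dimnames = list(source = srcs, target = tgts))
    rel <- records[records$reliable, , drop = FALSE]
    if (nrow(rel))
        for (i in seq_len(nrow(rel)))
            m[rel$source[i], rel$target[i]] <-
                m[rel$source[i], rel$target[i]] + 1L
    m
}

#' Select population-biased ligand-receptor interactions
#'
#' Compares, pair by pair, the median interaction score from source
#' population A toward a target with the median from source population B
#' toward the same target. A pair is called A-biased iff (i) the
#' difference of medians exceeds `delta` (strict), (ii) the gated gene
#' (the ligand for CAF-to-cancer directions, the receptor when the CAF
#' populations are the targets) is differentially expressed toward A
#' (adjusted p < `fdr` and FC > `fc`, both strict), and (iii) the larger
#' median passes the reliability gate (> 0.5). Symmetrically for B. The
#' two sets are disjoint by construction.
#'
#' @param recordsA,recordsB records from [scoreLRInteractions()] for the
#'   two directions being compared (same target population; sources A and
#'   B, or targets A and B when `gateGene = "receptor"`).
#' @param de [DEResult-class] of population A versus population B (A as
#'   group A), used for the gene gate.
#' @param delta minimum difference between median scores (strict).
#' @param fdr adjusted-p bound (strict).
#' @param fc fold-change bound (strict).
#' @param gateGene `"ligand"` or `"receptor"`: which gene of the pair must
#'   be differentially expressed between the two populations.
#' @return list with `A` and `B`: data.frames of the biased records with
#'   `deltaMedian` columns.
#' @export
biasedInteractions <- function(recordsA, recordsB, de,
                               delta = 0.1, fdr = 0.01, fc = 2,
                               gateGene = c("ligand", "receptor")) {
    gateGene <- match.arg(gateGene)
    key <- function(r) paste(r$ligand, r$receptor, sep = "~")
    a <- recordsA; b <- recordsB
    ka <- key(a); kb <- key(b)
    common <- intersect(ka, kb)
    a <- a[match(common, ka), , drop = FALSE]
    b <- b[match(common, kb), , drop = FALSE]
    dmed <- a$median - b$median
    gene <- if (gateGene == "ligand") a$ligand else a$receptor
    lfc <- setNames(de$log2FC, rownames(de))[gene]
    padj <- setNames(de$padj, rownames(de))[gene]
    deA <- !is.na(lfc) & 2^lfc > fc & padj < fdr
    deB <- !is.na(lfc) & 2^(-lfc) > fc & padj < fdr
    selA <- dmed > delta & deA & a$median > 0.5
    selB <- -dmed > delta & deB & b$median > 0.5
    outA <- cbind(a[selA, , drop = FALSE], deltaMedian = dmed[selA])
    outB <- cbind(b[selB, , drop = FALSE], deltaMedian = -dmed[selB])
    list(A = outA, B = outB)
}
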
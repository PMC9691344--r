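#' Differential expression for a two-condition bulk experiment
#'
#' Delegates to the shared TMM + negative-binomial engine with replicates
#' as libraries, and flags the significant set at the study gates
#' (adjusted p < 0.01 and |FC| > 2, both strict).
#'
#' @param counts genes x samples raw count table.
#' @param group condition label per sample (two conditions, >= 2
#'   replicates each).
#' @param groupA numerator condition (default: the second level).
#' @param padjMax,fcMin significance gates.
#' @return A [DEResult-class] with an extra logical column `significant`.
#' @export
bulkDE <- function(counts, group, groupA = NULL,
                   padjMax = 0.01, fcMin = 2) {
    group <- as.character(group)
    if (min(table(group)) < 2L)
        stop("each condition needs at least two replicates")
    res <- nbLRT(as.matrix(counts), group, groupA = groupA)
    res$significant <- !res$allZero & res$padj < padjMax &
        2^abs(res$log2FC) > fcMin
    res
}

#' Per-gene z-scores of TMM-normalized, log-transformed expression
#'
#' Counts are scaled by TMM-adjusted effective library sizes (counts per
#' million), transformed as `log2(x + 1)`, and standardized per gene
#' across samples using the sample standard deviation (n - 1). Constant
#' genes get z = 0.
#'
#' @param counts genes x samples raw count table.
#' @return genes x samples matrix of z-scores (row mean 0, row sd 1 for
#'   non-constant genes).
#' @export
zscoreTransform <- function(counts) {
    counts <- as.matrix(counts)
    f <- tmmFactors(counts)
    norm <- edgeR::cpm(edgeR::DGEList(counts = counts, norm.factors = f))
    lg <- log2(norm + 1)
    mu <- rowMeans(lg)
    s <- apply(lg, 1L, sd)
    z <- (lg - mu) / ifelse(s > 0, s, 1)
    z[s == 0, ] <- 0
    z
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (term, description, genes; tab-separated).
#' @return Named list of character vectors (term -> genes); descriptions
#'   in the `"descriptions"` attribute.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    terms <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
    names(terms) <- vapply(fields, `[`, "", 1L)
    attr(terms, "descriptions") <- vapply(fields, `[`, "", 2L)
    terms
}

#' Hypergeometric gene-set enrichment of a DE gene list
#'
#' Upper-tail hypergeometric test per term, restricted to terms containing
#' at least `minDE` (3) differentially expressed genes; terms below that
#' bound are absent from the output. BH-adjusted p-values are reported
#' alongside, but significance calls conventionally use the raw p.
#'
#' @param deGenes character vector of DE genes (must lie in `universe`).
#' @param universe character vector: the tested gene universe.
#' @param terms named list of gene sets (e.g. from [readGMT()]); genes
#'   outside the universe are ignored.
#' @param minDE minimum DE genes in a term for it to be tested.
#' @return `data.frame` with `term`, `termSize`, `nDEInTerm`, `p`, `padj`,
#'   sorted by `p`.
#' @export
goEnrichment <- function(deGenes, universe, terms, minDE = 3L) {
    universe <- unique(universe)
    deGenes <- unique(deGenes)
    if (!all(deGenes %in% universe))
        stop("deGenes must be a subset of the universe")
    N <- length(universe); n <- length(deGenes)
    rows <- lapply(names(terms), function(tm) {
        tg <- intersect(terms[[tm]], universe)
        k <- length(intersect(tg, deGenes))
        if (k < minDE) return(NULL)
        data.frame(term = tm, termSize = length(tg), nDEInTerm = k,
                   p = phyper(k - 1L, length(tg), N - length(tg), n,
                              lower.tail = FALSE),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(term = character(), termSize = integer(),
                          nDEInTerm = integer(), p = numeric(),
                          padj = numeric(), stringsAsFactors = FALSE))
    out$padj <- bhAdjust(out$p)
    out[order(out$p, out$term), , drop = FALSE]
}

#' Run the full bulk silencing stage
#'
#' DE calling at the study gates, z-score transformation of the normalized
#' expression of the significant genes, and gene-set enrichment of the DE
#' list.
#'
#' @inheritParams bulkDE
#' @param terms named list of gene sets (optional; enrichment skipped when
#'   `NULL`).
#' @return list with `de` ([DEResult-class]), `zscores` (significant genes
#'   only) and `enrichment`.
#' @export
bulkSilencingAnalysis <- function(counts, group, groupA = NULL,
                                  terms = NULL, padjMax = 0.01, fcMin = 2) {
    de <- bulkDE(counts, group, groupA, padjMax, fcMin)
    sig <- rownames(de)[de$significant]
    z <- zscoreTransform(counts)[sig, , drop = FALSE]
    enr <- NULL
    if (!is.null(terms)) {
        universe <- rownames(de)[!de$allZero]
        enr <- goEnrichment(intersect(sig, universe), universe, terms)
    }
    list(de = de, zscores = z, enrichment = enr)
}
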
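#' @importFrom stats predict
NULL

## Euclidean distances between columns of train and columns of query,
## via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
.euclid2 <- function(train, query) {
    d2 <- outer(colSums(train^2), colSums(query^2), `+`) -
        2 * crossprod(train, query)
    pmax(d2, 0)
}

#' Train a reference-origin classifier
#'
#' Fits one of three engines on labeled reference (atlas) cells:
#' `"randomForest"` (defaults), `"knn"` (k = 100, Euclidean on
#' log-normalized values without per-feature normalization, majority vote
#' with ties broken toward the smallest class index), or `"svmLinear"`
#' (features centered and scaled on the training set; cost selected by
#' internal repeated 10-fold cross-validation over a small grid).
#'
#' @param ref genes x cells matrix of log-normalized reference values, or
#'   a `SingleCellExperiment` with `logcounts`.
#' @param labels class label per reference cell.
#' @param engine one of `"randomForest"`, `"knn"`, `"svmLinear"`.
#' @param features feature genes (e.g. the union of the atlas signature
#'   genes restricted to genes present in the query data).
#' @param k neighbors for the kNN engine (clipped to the number of
#'   training cells with a warning).
#' @param svmCost cost grid for the SVM tuner; a single value skips
#'   tuning.
#' @param svmFolds,svmRepeats internal cross-validation design of the SVM
#'   tuner.
#' @param seed integer seed (forest bootstrap and tuner folds).
#' @return An [OriginModel-class].
#' @export
trainOriginModel <- function(ref, labels,
                             engine = c("randomForest", "knn", "svmLinear"),
                             features = NULL, k = 100L,
                             svmCost = c(0.1, 1, 10),
                             svmFolds = 10L, svmRepeats = 3L, seed = 1L) {
    engine <- match.arg(engine)
    mat <- if (is(ref, "SummarizedExperiment")) as.matrix(logcounts(ref))
           else as.matrix(ref)
    labels <- factor(as.character(labels))
    stopifnot(length(labels) == ncol(mat))
    if (any(table(labels) < 1L) || nlevels(labels) < 2L)
        stop("need at least two classes with cells")
    if (is.null(features)) features <- rownames(mat)
    if (!all(features %in% rownames(mat)))
        stop("feature gene(s) absent from the reference matrix")
    x <- mat[features, , drop = FALSE]
    set.seed(as.integer(seed))
    fit <- switch(engine,
        randomForest = randomForest::randomForest(x = t(x), y = labels),
        knn = {
            if (k > ncol(x)) {
                warning("k = ", k, " clipped to the ", ncol(x),
                        " training cells")
                k <- ncol(x)
            }
            list(train = x, labels = labels, k = as.integer(k))
        },
        svmLinear = {
            ctr <- rowMeans(x)
            scl <- apply(x, 1L, sd)
            scl[scl == 0] <- 1
            xs <- t((x - ctr) / scl)
            cost <- if (length(svmCost) > 1L)
                .tuneSVMCost(xs, labels, svmCost, svmFolds, svmRepeats)
            else svmCost
            list(svm = e1071::svm(x = xs, y = labels, kernel = "linear",
                                  cost = cost, scale = FALSE),
                 cost = cost, ctr = ctr, scl = scl)
        })
    ctr <- if (engine == "svmLinear") fit$ctr else numeric()
    scl <- if (engine == "svmLinear") fit$scl else numeric()
    new("OriginModel", engine = engine, features = features,
        classes = levels(labels), fit = fit, center = ctr, scale = scl)
}

## repeated stratified k-fold CV over a cost grid; highest mean accuracy,
## ties toward the smaller cost
.tuneSVMCost <- function(xs, labels, grid, folds, repeats) {
    acc <- sapply(grid, function(cost) {
        hits <- 0L; total <- 0L
        for (r in seq_len(repeats)) {
            foldId <- unlist(lapply(split(seq_along(labels), labels),
                function(idx) sample(rep_len(seq_len(folds), length(idx)))))
            idxAll <- unlist(split(seq_along(labels), labels))
            for (f in seq_len(folds)) {
                test <- idxAll[foldId == f]
                if (length(test) == 0L || length(test) == length(labels))
                    next
                m <- e1071::svm(x = xs[-test, , drop = FALSE],
                                y = labels[-test], kernel = "linear",
                                cost = cost, scale = FALSE)
                pred <- predict(m, xs[test, , drop = FALSE])
                hits <- hits + sum(pred == labels[test])
                total <- total + length(test)
            }
        }
        hits / total
    })
    grid[which.max(acc)]
}

#' Predict reference origins for query cells
#'
#' @param model an [OriginModel-class].
#' @param query genes x cells matrix of log-normalized values or a
#'   `SingleCellExperiment`; must contain every feature gene of the model
#'   (no silent imputation).
#' @return Factor of predicted classes, one per query cell.
#' @export
predictOrigin <- function(model, query) {
    mat <- if (is(query, "SummarizedExperiment")) as.matrix(logcounts(query))
           else as.matrix(query)
    missing <- setdiff(model@features, rownames(mat))
    if (length(missing))
        stop("query matrix lacks feature gene(s): ",
             paste(utils::head(missing, 5L), collapse = ", "))
    x <- mat[model@features, , drop = FALSE]
    out <- switch(model@engine,
        randomForest = predict(model@fit, t(x)),
        knn = {
            d2 <- .euclid2(model@fit$train, x)
            k <- model@fit$k
            lab <- model@fit$labels
            cls <- levels(lab)
            pred <- apply(d2, 2L, function(col) {
                nn <- lab[order(col)[seq_len(k)]]
                votes <- table(nn)
                cls[which.max(votes)]  # ties: smallest class index
            })
            factor(pred, levels = cls)
        },
        svmLinear = {
            xs <- t((x - model@center) / model@scale)
            predict(model@fit$svm, xs)
        })
    factor(as.character(out), levels = model@classes)
}

#' Cross-validate an origin classifier
#'
#' Stratified random splits: `trainFrac` of the cells of each class train
#' the model, the remainder tests it; repeated `repeats` times. The split
#' sequence is a deterministic function of `seed`.
#'
#' @inheritParams trainOriginModel
#' @param trainFrac training fraction (0.9).
#' @param repeats number of repeats (20).
#' @param ... passed to [trainOriginModel()].
#' @return list with `accuracy` (per repeat), `meanAccuracy`,
#'   `sdAccuracy`, and `perClass` (mean per-class accuracy).
#' @export
crossValidateOrigin <- function(ref, labels, engine = "randomForest",
                                features = NULL, trainFrac = 0.9,
                                repeats = 20L, seed = 1L, ...) {
    mat <- if (is(ref, "SummarizedExperiment")) as.matrix(logcounts(ref))
           else as.matrix(ref)
    labels <- factor(as.character(labels))
    set.seed(as.integer(seed))
    splitSeeds <- sample.int(.Machine$integer.max, repeats)
    acc <- numeric(repeats)
    perClass <- matrix(0, repeats, nlevels(labels),
                       dimnames = list(NULL, levels(labels)))
    for (r in seq_len(repeats)) {
        set.seed(splitSeeds[r])
        testIdx <- unlist(lapply(split(seq_along(labels), labels),
            function(idx) {
                nTest <- max(1L, round((1 - trainFrac) * length(idx)))
                sample(idx, nTest)
            }))
        model <- trainOriginModel(mat[, -testIdx, drop = FALSE],
                                  labels[-testIdx], engine = engine,
                                  features = features,
                                  seed = splitSeeds[r], ...)
        pred <- predictOrigin(model, mat[, testIdx, drop = FALSE])
        truth <- labels[testIdx]
        acc[r] <- mean(pred == truth)
        perClass[r, ] <- vapply(levels(labels), function(cl)
            mean(pred[truth == cl] == cl), numeric(1))
    }
    list(accuracy = acc, meanAccuracy = mean(acc), sdAccuracy = sd(acc),
         perClass = colMeans(perClass))
}

#' Assign reference origins to CAF populations
#'
#' Predicts a closest reference phenotype for every CAF and tabulates, per
#' CAF population, the fraction of cells assigned to each reference class.
#'
#' @param model an [OriginModel-class] (or named list of models, in which
#'   case the per-cell majority vote across engines is used, ties broken
#'   by the first engine's call).
#' @param caf query matrix or `SingleCellExperiment` (log-normalized).
#' @param populations CAF population label per query cell.
#' @return list with `table` (populations x classes assignment-rate
#'   matrix; rows sum to 1), `n` (cells per population) and `cellLabels`.
#' @export
assignOrigin <- function(model, caf, populations) {
    models <- if (is(model, "OriginModel")) list(model) else model
    preds <- lapply(models, predictOrigin, query = caf)
    classes <- models[[1L]]@classes
    pred <- if (length(preds) == 1L) preds[[1L]] else {
        votes <- do.call(cbind, lapply(preds, as.character))
        factor(apply(votes, 1L, function(v) {
            tb <- table(factor(v, levels = classes))
            top <- names(tb)[tb == max(tb)]
            if (v[1L] %in% top) v[1L] else top[1L]
        }), levels = classes)
    }
    pops <- if (is.factor(populations)) levels(populations)
            else unique(as.character(populations))
    populations <- as.character(populations)
    counts <- table(factor(populations, levels = pops),
                    factor(pred, levels = classes))
    n <- rowSums(counts)
    if (any(n == 0L)) {
        warning("population(s) with 0 cells omitted: ",
                paste(rownames(counts)[n == 0L], collapse = ", "))
        counts <- counts[n > 0L, , drop = FALSE]
        n <- n[n > 0L]
    }
    rates <- sweep(unclass(counts), 1L, n, `/`)
    list(table = rates, n = n, cellLabels = pred)
}

#' Multinomial goodness-of-fit test against fixed proportions
#'
#' Likelihood-ratio (G) statistic of observed class counts against given
#' proportions, referred to \eqn{\chi^2(k-1)}; for small totals
#' (`n <= exactMax`) the exact tail is computed by enumerating all
#' outcomes and summing the probability of those at least as extreme
#' (G >= observed G).
#'
#' @param counts integer vector of class counts.
#' @param probs null class proportions (normalized internally).
#' @param exactMax largest total for which exact enumeration is used.
#' @return list with `statistic`, `p`, `method`.
#' @export
multinomialGOFTest <- function(counts, probs, exactMax = 50L) {
    counts <- as.integer(counts)
    n <- sum(counts)
    if (n == 0L) stop("empty group: no counts to test")
    probs <- probs / sum(probs)
    stopifnot(length(counts) == length(probs), all(probs > 0))
    G <- function(x) {
        e <- sum(x) * probs
        2 * sum(ifelse(x > 0, x * log(x / e), 0))
    }
    gObs <- G(counts)
    if (n <= exactMax) {
        comps <- .compositions(n, length(counts))
        gAll <- apply(comps, 1L, G)
        pAll <- apply(comps, 1L, function(x) stats::dmultinom(x, prob = probs))
        p <- sum(pAll[gAll >= gObs - 1e-9])
        list(statistic = gObs, p = p, method = "exact")
    } else {
        list(statistic = gObs,
             p = pchisq(gObs, df = length(counts) - 1L, lower.tail = FALSE),
             method = "chisq")
    }
}

## all compositions of n into k non-negative parts
.compositions <- function(n, k) {
    if (k == 1L) return(matrix(n, 1L, 1L))
    out <- lapply(0:n, function(i)
        cbind(i, .compositions(n - i, k - 1L)))
    do.call(rbind, out)
}

#' Pairwise multinomial composition test between groups
#'
#' For each pair of groups, tests whether their origin-class compositions
#' differ, by a likelihood-ratio G-test of the 2 x k table against the
#' pooled proportions (df = k - 1), with exact enumeration under the
#' pooled null when the combined total is at most `exactMax`.
#'
#' @param counts groups x classes matrix of origin counts.
#' @param exactMax combined-total bound for exact enumeration.
#' @return Symmetric matrix of p-values (diagonal `NA`).
#' @export
compositionMultinomialTest <- function(counts, exactMax = 50L) {
    counts <- as.matrix(counts)
    if (any(rowSums(counts) == 0))
        stop("group(s) with zero total count")
    g <- nrow(counts); k <- ncol(counts)
    p <- matrix(NA_real_, g, g, dimnames = list(rownames(counts),
                                                rownames(counts)))
    G2 <- function(x, y, probs) {
        gx <- 2 * sum(ifelse(x > 0, x * log(x / (sum(x) * probs)), 0))
        gy <- 2 * sum(ifelse(y > 0, y * log(y / (sum(y) * probs)), 0))
        gx + gy
    }
    for (i in seq_len(g)) for (j in seq_len(g)) if (i < j) {
        x <- counts[i, ]; y <- counts[j, ]
        pooled <- (x + y) / sum(x + y)
        pooled[pooled == 0] <- .Machine$double.eps
        gObs <- G2(x, y, pooled)
        if (sum(x) + sum(y) <= exactMax) {
            cx <- .compositions(sum(x), k); cy <- .compositions(sum(y), k)
            px <- apply(cx, 1L, function(v) stats::dmultinom(v, prob = pooled))
            py <- apply(cy, 1L, function(v) stats::dmultinom(v, prob = pooled))
            gx <- apply(cx, 1L, function(v)
                2 * sum(ifelse(v > 0, v * log(v / (sum(v) * pooled)), 0)))
            gy <- apply(cy, 1L, function(v)
                2 * sum(ifelse(v > 0, v * log(v / (sum(v) * pooled)), 0)))
            tail <- outer(gx, gy, `+`) >= gObs - 1e-9
            p[i, j] <- p[j, i] <- sum(outer(px, py) * tail)
        } else {
            p[i, j] <- p[j, i] <-
                pchisq(gObs, df = k - 1L, lower.tail = FALSE)
        }
    }
    p
}
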
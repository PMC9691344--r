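## small separable atlas for classifier tests
makeAtlas <- function(nPer = 60L, seed = 1L) {
    atl <- simulateReferenceAtlas(
        simConfig(nGenes = 300L, nCellsPerSample = nPer, seed = seed))
    normalizeLog(atl)
}

test_that("kNN with k = 1 returns the class of the matching training cell", {
    m <- matrix(c(0, 0, 10, 0, 0, 10), 2, 3,
                dimnames = list(c("g1", "g2"), c("a", "b", "c")))
    model <- trainOriginModel(m, c("X", "Y", "Z"), "knn", k = 1L)
    pred <- predictOrigin(model, m[, "b", drop = FALSE])
    expect_identical(as.character(pred), "Y")
})

test_that("k is clipped to the training size and features must be present", {
    m <- matrix(rnorm(20 * 10), 20, 10,
                dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
    lab <- rep(c("X", "Y"), 5)
    expect_warning(model <- trainOriginModel(m, lab, "knn", k = 100L),
                   "clipped")
    expect_identical(model@fit$k, 10L)
    q <- m[1:15, , drop = FALSE]
    expect_error(predictOrigin(model, q), "lacks feature")
    expect_error(trainOriginModel(m, lab, "knn", features = "nope"),
                 "absent")
})

test_that("all engines separate a planted atlas", {
    atl <- makeAtlas(seed = 2L)
    amat <- as.matrix(logcounts(atl))
    feats <- unique(S4Vectors::metadata(atl)$truth$markerTable$gene)
    for (eng in c("randomForest", "knn", "svmLinear")) {
        model <- trainOriginModel(amat, atl$population, eng,
                                  features = feats, seed = 3L)
        acc <- mean(predictOrigin(model, amat) == atl$population)
        expect_gte(acc, 0.99)
    }
})

test_that("cross-validation is seed-deterministic and chance-level on shuffled labels", {
    atl <- makeAtlas(seed = 4L)
    amat <- as.matrix(logcounts(atl))
    feats <- unique(S4Vectors::metadata(atl)$truth$markerTable$gene)
    cv1 <- crossValidateOrigin(amat, atl$population, "knn",
                               features = feats, repeats = 5L, seed = 7L)
    cv2 <- crossValidateOrigin(amat, atl$population, "knn",
                               features = feats, repeats = 5L, seed = 7L)
    expect_identical(cv1$accuracy, cv2$accuracy)
    expect_gte(cv1$meanAccuracy, 0.95)

    set.seed(8)
    shuffled <- sample(as.character(atl$population))
    cv0 <- crossValidateOrigin(amat, shuffled, "knn", features = feats,
                               repeats = 10L, seed = 9L)
    nTest <- 10 * ceiling(0.1 * ncol(amat))
    tol <- 3 * sqrt((1 / 3) * (2 / 3) / nTest)
    expect_lt(abs(cv0$meanAccuracy - 1 / 3), tol)
})

test_that("assignment rates are row-normalized and queries of one class map back", {
    atl <- makeAtlas(seed = 5L)
    amat <- as.matrix(logcounts(atl))
    feats <- unique(S4Vectors::metadata(atl)$truth$markerTable$gene)
    model <- trainOriginModel(amat, atl$population, "knn", features = feats)
    ## query identical to the VSMC reference cells
    q <- amat[, atl$population == "VSMC"]
    asg <- assignOrigin(model, q, rep("Q", ncol(q)))
    expect_equal(unname(asg$table["Q", "VSMC"]), 1)
    expect_equal(unname(rowSums(asg$table)), 1, tolerance = 1e-9)

    ## empty population (unused factor level) is dropped with a warning
    pops <- factor(rep("Q", ncol(q)), levels = c("Q", "ghost"))
    expect_warning(asg2 <- assignOrigin(model, q, pops), "0 cells")
    expect_identical(rownames(asg2$table), "Q")
})

test_that("majority vote across engines matches the unanimous call", {
    atl <- makeAtlas(seed = 6L)
    amat <- as.matrix(logcounts(atl))
    feats <- unique(S4Vectors::metadata(atl)$truth$markerTable$gene)
    models <- lapply(c("randomForest", "knn"), function(e)
        trainOriginModel(amat, atl$population, e, features = feats,
                         seed = 2L))
    asg <- assignOrigin(models, amat, atl$population)
    expect_gte(mean(diag(asg$table[c("HSC", "SAMes", "VSMC"),
                                   c("HSC", "SAMes", "VSMC")])), 0.99)
})

test_that("multinomial GOF test matches exact enumeration and its asymptotics", {
    ## extreme table: exact tail is the probability of the three
    ## one-category outcomes
    r <- multinomialGOFTest(c(10, 0, 0), rep(1 / 3, 3))
    expect_identical(r$method, "exact")
    expect_equal(r$p, 3 * (1 / 3)^10, tolerance = 1e-12)

    ## identical proportions, large n: statistic ~ 0, p ~ 1
    r1 <- multinomialGOFTest(c(300, 300, 300), rep(1 / 3, 3))
    expect_identical(r1$method, "chisq")
    expect_gt(r1$p, 0.99)

    expect_error(multinomialGOFTest(c(0, 0, 0), rep(1 / 3, 3)), "empty")

    ## exact and chi-square agree for balanced moderate tables
    cnt <- c(75, 70, 55)
    ex <- multinomialGOFTest(cnt, rep(1 / 3, 3), exactMax = 250L)
    ch <- multinomialGOFTest(cnt, rep(1 / 3, 3), exactMax = 0L)
    expect_lt(abs(ex$p - ch$p) / ex$p, 0.1)
})

test_that("pairwise composition test sees identical and divergent groups", {
    tab <- rbind(g1 = c(400, 300, 300), g2 = c(400, 300, 300))
    p <- compositionMultinomialTest(tab)
    expect_gt(p["g1", "g2"], 0.99)

    tab2 <- rbind(g1 = c(500, 100, 100), g2 = c(100, 500, 100))
    p2 <- compositionMultinomialTest(tab2)
    expect_lt(p2["g1", "g2"], 1e-10)

    ## small totals: exact enumeration under the pooled null
    tab3 <- rbind(g1 = c(10, 2, 2), g2 = c(2, 10, 2))
    p3 <- compositionMultinomialTest(tab3)
    expect_true(p3["g1", "g2"] > 0 && p3["g1", "g2"] < 0.05)

    expect_error(compositionMultinomialTest(rbind(c(0, 0, 0), c(1, 2, 3))),
                 "zero total")
})
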
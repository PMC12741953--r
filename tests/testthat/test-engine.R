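test_that("jointObserved keeps exactly the jointly non-missing pairs", {
    m <- NaN
    o <- jointObserved(c(1, m, 3, 4), c(m, 2, 5, 6))
    expect_equal(o$g, c(3, 4))
    expect_equal(o$h, c(5, 6))
    expect_equal(o$n, 2)
    expect_equal(jointObserved(c(m, m), c(1, 2))$n, 0)
    full <- runif(9)
    expect_equal(jointObserved(full, full)$n, 9)
    # finite sentinel
    o <- jointObserved(c(1, -9, 3), c(4, 5, -9), naValue = -9)
    expect_equal(o$n, 1)
    expect_error(jointObserved(1:3, 1:4), "equal length")
})

test_that("n_used equals samples minus the union of missing positions", {
    set.seed(11)
    for (rep in 1:20) {
        S <- sample(5:40, 1)
        g <- runif(S)
        h <- runif(S)
        g[sample(S, sample(0:S, 1))] <- NaN
        h[sample(S, sample(0:S, 1))] <- NaN
        expect_equal(jointObserved(g, h)$n,
                     S - sum(is.na(g) | is.na(h)))
    }
})

test_that("presorted subset re-ranking equals ranking from scratch", {
    set.seed(3)
    v <- sample(round(runif(30), 1))  # plenty of ties
    v[c(4, 9)] <- NaN
    m <- MixedMatrix(matrix(v, 1))
    ord <- presortFeatures(m)[[1]]
    expect_true(all(diff(v[ord]) >= 0))
    for (rep in 1:10) {
        keep <- !is.na(v) & runif(30) > 0.3
        expect_equal(pairstat:::.subsetRanks(v, ord, keep),
                     rank(v[keep], ties.method = "average"))
    }
    # features with < 2 observed values give trivial orders
    expect_length(presortFeatures(MixedMatrix(matrix(c(NaN, 5), 1)))[[1]], 1)
})

test_that("presort example gives the ascending-value order", {
    m <- MixedMatrix(matrix(c(3, 1, 2), 1))
    expect_equal(presortFeatures(m)[[1]], c(2, 3, 1))
})

test_that("homogeneous bundles are symmetric with self-test diagonals", {
    x <- makeMatrix("continuous", 8, 30, missRate = 0.2, seed = 5)
    b <- runPairwise("pearson", x,
                     outputs = c("statistic", "p_unadjusted",
                                 "p_bonferroni", "r2"))
    s <- b[["statistic"]]
    expect_identical(s, t(s))
    expect_identical(b[["p_unadjusted"]], t(b[["p_unadjusted"]]))
    expect_equal(unname(diag(s)), rep(1, 8))          # self-test r = 1
    expect_equal(unname(diag(b[["p_unadjusted"]])), rep(0, 8))
    expect_true(all(is.nan(diag(b[["p_bonferroni"]]))))  # self-tests excluded
})

test_that("results are identical for any thread count", {
    x <- makeMatrix("continuous", 12, 50, missRate = 0.3, seed = 9)
    outs <- c("statistic", "p_unadjusted", "p_benjamini_hochberg", "r2")
    b1 <- runPairwise("pearson", x, threads = 1, outputs = outs)
    b2 <- runPairwise("pearson", x, threads = 2, outputs = outs)
    b8 <- runPairwise("pearson", x, threads = 8, outputs = outs)
    expect_identical(as.list(b1), as.list(b2))
    expect_identical(as.list(b1), as.list(b8))
    d <- makeMatrix("dichotomous", 6, 50, missRate = 0.3, seed = 10)
    y <- makeMatrix("continuous", 7, 50, missRate = 0.3, seed = 11)
    w1 <- runPairwise("mwu", d, y, threads = 1)
    w8 <- runPairwise("mwu", d, y, threads = 8)
    expect_identical(as.list(w1), as.list(w8))
})

test_that("requested outputs are validated and shape the bundle", {
    x <- makeMatrix("continuous", 4, 20, seed = 2)
    expect_error(runPairwise("pearson", x, outputs = c("statistic", "rho")),
                 "invalid output.*valid:")
    expect_error(runPairwise("pearson", x, outputs = character(0)),
                 "at least one")
    b <- runPairwise("pearson", x, outputs = "r2")
    expect_identical(resultNames(b), "r2")
    expect_setequal(availableOutputs("kruskal"),
                    c("statistic", "p_unadjusted", "p_bonferroni",
                      "p_benjamini_hochberg", "p_benjamini_yekutieli", "eta2"))
})

test_that("kind mismatches and sample mismatches are rejected", {
    cont <- makeMatrix("continuous", 3, 10, seed = 1)
    cat4 <- makeMatrix("categorical", 3, 10, seed = 1)
    expect_error(runPairwise("pearson", cat4), "requires 'x' of kind")
    expect_error(runPairwise("anova", cat4), "continuous MixedMatrix 'y'")
    expect_error(runPairwise("pearson", cont, cont), "single matrix")
    y2 <- makeMatrix("continuous", 3, 11, seed = 2)
    expect_error(runPairwise("anova", cat4, y2), "share the sample dimension")
})

test_that("mixed bundles have grouping features in rows", {
    d <- makeMatrix("dichotomous", 5, 25, seed = 3)
    y <- makeMatrix("continuous", 4, 25, seed = 4)
    b <- runPairwise("ttest", d, y, outputs = c("statistic", "cohens_d"))
    expect_identical(dim(b[["statistic"]]), c(5L, 4L))
    expect_identical(rownames(b[["statistic"]]), featureNames(d))
    expect_identical(colnames(b[["statistic"]]), featureNames(y))
})
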
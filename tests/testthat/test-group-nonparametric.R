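test_that("exact U distribution follows the counting recurrence", {
    expect_equal(mwuExactDistribution(1, 1)$freq, c(1, 1))
    d22 <- mwuExactDistribution(2, 2)
    expect_equal(d22$freq, c(1, 1, 2, 1, 1))
    expect_equal(sum(d22$freq), choose(4, 2))
    # symmetry and total count for a larger case
    d <- mwuExactDistribution(5, 4)
    expect_equal(sum(d$freq), choose(9, 5))
    expect_equal(d$freq, rev(d$freq))
    expect_error(mwuExactDistribution(200, 200, maxProduct = 1000),
                 "asymptotic")
    expect_error(mwuExactDistribution(0, 3), "at least 1")
})

test_that("Mann-Whitney exact, asymptotic and auto modes behave as specified", {
    r <- mwuPair(c(1, 2), c(3, 4), mode = "exact")
    expect_equal(r$statistic, 0)
    expect_equal(r$p, 1 / 3)

    # empty group: everything undefined
    e <- mwuPair(numeric(0), c(1, 2, 3))
    expect_true(is.nan(e$statistic) && is.nan(e$p))

    # exact mode refuses ties
    expect_error(mwuPair(c(1, 1, 2), c(2, 3, 4), mode = "exact"), "ties")

    # asymptotic with tie correction matches the reference implementation
    set.seed(43)
    x0 <- round(runif(15), 1)
    x1 <- round(runif(18), 1)
    got <- mwuPair(x0, x1, mode = "asymptotic")
    wt <- suppressWarnings(wilcox.test(x0, x1, exact = FALSE,
                                       correct = TRUE))
    expect_equal(got$statistic, unname(wt$statistic))
    expect_equal(got$p, wt$p.value, tolerance = 1e-12)

    # auto selects exact for small tie-free groups
    x0 <- runif(6)
    x1 <- runif(7)
    expect_equal(mwuPair(x0, x1, mode = "auto")$p,
                 wilcox.test(x0, x1, exact = TRUE)$p.value,
                 tolerance = 1e-12)
    # and asymptotic otherwise
    x0 <- runif(9)
    x1 <- runif(9)
    expect_equal(mwuPair(x0, x1, mode = "auto")$p,
                 wilcox.test(x0, x1, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-12)
})

test_that("U statistics of the two groups are complementary", {
    set.seed(47)
    x0 <- runif(7)
    x1 <- runif(5)
    u1 <- mwuPair(x0, x1)$statistic
    u2 <- mwuPair(x1, x0)$statistic
    expect_equal(u1 + u2, 7 * 5)
    expect_equal(mwuPair(x0, x1)$p, mwuPair(x1, x0)$p)
})

test_that("exact and asymptotic p-values converge at n1 = n2 = 20", {
    set.seed(53)
    for (rep in 1:5) {
        x0 <- runif(20)
        x1 <- runif(20, 0.1)
        pe <- mwuPair(x0, x1, mode = "exact")$p
        pa <- mwuPair(x0, x1, mode = "asymptotic")$p
        expect_lt(abs(pe - pa), 0.01)
    }
})

test_that("Kruskal-Wallis matches identical-group and reference cases", {
    r <- kruskalPair(list(c(1, 2, 3), c(1, 2, 3)))
    expect_equal(r$statistic, 0)
    expect_equal(r$p, 1)

    set.seed(59)
    g <- sample(1:3, 45, replace = TRUE)
    v <- round(rnorm(45) + 0.4 * g, 1)  # with ties
    got <- kruskalPair(split(v, g))
    kt <- kruskal.test(v, factor(g))
    expect_equal(got$statistic, unname(kt$statistic), tolerance = 1e-12)
    expect_equal(got$p, kt$p.value, tolerance = 1e-12)
})

test_that("Kruskal-Wallis degenerate contracts produce NaN", {
    expect_true(is.nan(kruskalPair(list(numeric(0), c(1, 2)))$statistic))
    # one sample per category: eta^2 undefined (H itself defined)
    r <- kruskalPair(list(1, 2, 3))
    expect_false(is.nan(r$statistic))
    expect_true(is.nan(r$effects[["eta2"]]))
    # all values tied: tie correction factor hits zero
    expect_true(is.nan(kruskalPair(list(c(1, 1), c(1, 1)))$statistic))
})

test_that("H equals z^2 for two tie-free groups without continuity", {
    set.seed(61)
    for (rep in 1:5) {
        x0 <- runif(11)
        x1 <- runif(13)
        h <- kruskalPair(list(x0, x1))$statistic
        # reconstruct z from the continuity-free asymptotic computation
        got <- pairstat:::.mwuFromRanks(rank(c(x0, x1)),
                                        rep(1:2, c(11, 13)),
                                        mode = "asymptotic",
                                        continuity = FALSE)
        n <- 24
        z <- (got[["statistic"]] - 11 * 13 / 2) /
            sqrt(11 * 13 * (n + 1) / 12)
        expect_equal(h, z^2, tolerance = 1e-6)
    }
})

test_that("rank tests are invariant under strictly increasing transforms", {
    set.seed(67)
    x0 <- runif(8)
    x1 <- runif(9)
    f <- function(v) exp(2 * v) - 1
    expect_equal(mwuPair(f(x0), f(x1))$statistic, mwuPair(x0, x1)$statistic)
    expect_equal(mwuPair(f(x0), f(x1))$p, mwuPair(x0, x1)$p)
    g <- list(runif(5), runif(6), runif(4))
    expect_equal(kruskalPair(lapply(g, f))$statistic,
                 kruskalPair(g)$statistic)
})
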
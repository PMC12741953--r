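test_that("Pearson handles perfect, random and degenerate pairs", {
    r <- pearsonPair(c(0, 1, 2), c(0, 1, 2))
    expect_equal(r$statistic, 1)
    expect_equal(r$effects[["r2"]], 1)
    expect_equal(r$p, 0)

    # degenerate contract: n <= 1 undefined, n == 2 gives r but no p,
    # zero variance undefined
    expect_true(all(is.nan(unlist(pearsonPair(5, 7)[c("statistic", "p")]))))
    r2 <- pearsonPair(c(1, 2), c(3, 5))
    expect_equal(r2$statistic, 1)
    expect_true(is.nan(r2$p))
    z <- pearsonPair(c(1, 1, 1), c(1, 2, 3))
    expect_true(is.nan(z$statistic) && is.nan(z$p))

    set.seed(21)
    x <- rnorm(30)
    y <- x + rnorm(30)
    ct <- cor.test(x, y)
    got <- pearsonPair(x, y)
    expect_equal(got$statistic, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-12)
})

test_that("Pearson p matches the reference over a grid of r at n = 10", {
    n <- 10
    for (rho in seq(-0.9, 0.9, by = 0.2)) {
        # construct data with exactly this correlation
        x <- scale(1:n)[, 1]
        e <- scale(resid(lm(rnorm(n) ~ x)))[, 1]
        y <- rho * x + sqrt(1 - rho^2) * e
        got <- pearsonPair(x, y)
        ct <- cor.test(x, y)
        expect_equal(got$statistic, unname(ct$estimate), tolerance = 1e-9)
        expect_equal(got$p, ct$p.value, tolerance = 1e-9)
    }
})

test_that("tie-averaged ranking follows the averaging definition", {
    expect_equal(rankWithTies(c(10, 20, 20, 30)), c(1, 2.5, 2.5, 4))
    expect_equal(rankWithTies(sort(runif(8))), as.numeric(1:8))
    expect_equal(rankWithTies(rep(3, 3)), rep(2, 2 + 1))
    # rank sums are always n(n+1)/2
    set.seed(4)
    for (rep in 1:10) {
        v <- sample(round(runif(17), 1))
        expect_equal(sum(rankWithTies(v)), 17 * 18 / 2)
    }
    expect_error(rankWithTies(c(1, NA)), "missing")
})

test_that("Spearman handles perfect, tied and degenerate pairs", {
    s <- spearmanPair(c(1, 2, 3, 4), c(4, 3, 2, 1))
    expect_equal(s$statistic, -1)
    expect_equal(s$p, 0)

    expect_true(is.nan(spearmanPair(1, 2)$statistic))
    s2 <- spearmanPair(c(1, 2), c(5, 9))
    expect_equal(s2$statistic, 1)
    expect_true(is.nan(s2$p))
    expect_true(is.nan(spearmanPair(c(2, 2, 2), c(1, 2, 3))$statistic))

    set.seed(31)
    x <- sample(round(runif(25), 1))  # injected ties
    y <- x + round(rnorm(25), 1)
    ct <- cor.test(x, y, method = "spearman", exact = FALSE)
    got <- spearmanPair(x, y)
    expect_equal(got$statistic, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-12)
})

test_that("correlations are invariant under monotone transforms", {
    set.seed(41)
    x <- runif(20)
    y <- runif(20)
    base_r <- pearsonPair(x, y)
    base_s <- spearmanPair(x, y)
    # affine transform leaves both invariant
    expect_equal(pearsonPair(3 * x + 2, y)$statistic, base_r$statistic)
    expect_equal(spearmanPair(3 * x + 2, y)$statistic, base_s$statistic)
    # non-linear strictly increasing transform leaves rho invariant
    expect_equal(spearmanPair(exp(x), y)$statistic, base_s$statistic)
    expect_equal(spearmanPair(exp(x), y)$p, base_s$p)
})

test_that("p decreases as |r| grows at fixed n", {
    n <- 12
    x <- scale(1:n)[, 1]
    e <- scale(resid(lm(rnorm(n) ~ x)))[, 1]
    ps <- vapply(seq(0.1, 0.9, by = 0.1), function(rho)
        pearsonPair(x, rho * x + sqrt(1 - rho^2) * e)$p, numeric(1))
    expect_true(all(diff(ps) < 0))
    expect_true(all(ps >= 0 & ps <= 1))
})
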
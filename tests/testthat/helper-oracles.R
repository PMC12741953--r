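# Independent scalar oracles (base R reference routines applied after
# manual pairwise deletion) and fixture builders shared across tests.

# ---- fixtures --------------------------------------------------------------

# simulated matrices with per-feature MCAR missingness, built through the
# package's own generator (itself tested in test-simulator.R)
makeMatrix <- function(kind, nf, ns, missRate = 0, seed = 1, nCategories = 4) {
    m <- simulateMatrix(nf, ns, kind = kind, nCategories = nCategories,
                        seed = seed)
    if (missRate > 0)
        m <- injectMissing(m, missRate, "MCAR", seed = seed + 10000L)
    m
}

# ---- scalar oracles (reference routines, manual deletion done by caller) ---

oracleCell <- function(test, a, b, labsA = NULL, labsB = NULL,
                       variant = "student") {
    ok <- !is.na(a) & !is.na(b)
    x <- a[ok]
    y <- b[ok]
    safely <- function(expr) tryCatch(expr, error = function(e) NULL)
    res <- switch(test,
        pearson = safely({
            ct <- cor.test(x, y)
            c(unname(ct$estimate), ct$p.value)
        }),
        spearman = safely({
            ct <- cor.test(x, y, method = "spearman", exact = FALSE)
            c(unname(ct$estimate), ct$p.value)
        }),
        chi2 = safely({
            tab <- table(factor(x, levels = labsA), factor(y, levels = labsB))
            if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) NULL
            else {
                ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
                c(unname(ct$statistic), ct$p.value)
            }
        }),
        ttest = safely({
            x0 <- y[x == 0]
            x1 <- y[x == 1]
            if (length(x0) < 2 || length(x1) < 2) NULL
            else {
                ct <- t.test(x0, x1, var.equal = (variant == "student"))
                c(unname(ct$statistic), ct$p.value)
            }
        }),
        mwu = safely({
            x0 <- y[x == 0]
            x1 <- y[x == 1]
            if (length(x0) == 0 || length(x1) == 0) NULL
            else {
                # same selection rule as the package's auto mode, applied to
                # the reference implementation (which has no auto mode)
                exact <- !any(duplicated(c(x0, x1))) &&
                    min(length(x0), length(x1)) < 8
                ct <- suppressWarnings(
                    wilcox.test(x0, x1, exact = exact, correct = TRUE))
                c(unname(ct$statistic), ct$p.value)
            }
        }),
        anova = safely({
            g <- factor(x, levels = labsA)
            if (any(table(g) == 0)) NULL
            else {
                ct <- oneway.test(y ~ g, var.equal = TRUE)
                c(unname(ct$statistic), ct$p.value)
            }
        }),
        kruskal = safely({
            g <- factor(x, levels = labsA)
            if (any(table(g) == 0)) NULL
            else {
                ct <- kruskal.test(y, g)
                c(unname(ct$statistic), ct$p.value)
            }
        }))
    if (is.null(res)) c(NA_real_, NA_real_) else res
}

observedLabels <- function(v) sort(unique(v[!is.na(v)]))

# engine-vs-oracle sweep over every cell of one dataset; compares statistic
# and p wherever both sides are defined
expectEngineMatchesOracle <- function(test, missRate, seed, tol,
                                      nf = 15, ns = 40, variant = "student") {
    homogeneous <- test %in% c("pearson", "spearman", "chi2")
    xkind <- switch(test, pearson = , spearman = "continuous",
                    chi2 = , anova = , kruskal = "categorical",
                    ttest = , mwu = "dichotomous")
    x <- makeMatrix(xkind, nf, ns, missRate, seed)
    y <- if (homogeneous) NULL
         else makeMatrix("continuous", nf, ns, missRate, seed + 500L)
    bundle <- runPairwise(test, x, y, variant = variant)
    stat <- bundle[["statistic"]]
    pv <- bundle[["p_unadjusted"]]
    X <- values(x)
    eng <- orc <- numeric(0)
    cells <- if (homogeneous) {
        idx <- which(upper.tri(stat), arr.ind = TRUE)
        lapply(seq_len(nrow(idx)), function(r) idx[r, ])
    } else {
        Y <- values(y)
        expand.grid(row = seq_len(nf), col = seq_len(nf)) |>
            (\(d) lapply(seq_len(nrow(d)), function(r) unlist(d[r, ])))()
    }
    for (cl in cells) {
        i <- cl[[1]]
        j <- cl[[2]]
        a <- X[i, ]
        b <- if (homogeneous) X[j, ] else values(y)[j, ]
        o <- oracleCell(test, a, b,
                        labsA = observedLabels(a),
                        labsB = observedLabels(b),
                        variant = variant)
        e <- c(stat[i, j], pv[i, j])
        keep <- !is.na(o) & !is.na(e)
        eng <- c(eng, e[keep])
        orc <- c(orc, o[keep])
    }
    expect_gt(length(eng), 0)
    expect_equal(eng, orc, tolerance = tol)
}

# ---- independent multiple-testing oracle (hand-written formulas) -----------

oracleAdjust <- function(p, method) {
    m <- length(p)
    if (method == "bonferroni")
        return(pmin(1, p * m))
    o <- order(p)
    ro <- order(o)
    fac <- if (method == "by") sum(1 / seq_len(m)) else 1
    q <- p[o] * fac * m / seq_len(m)
    pmin(1, rev(cummin(rev(q))))[ro]
}

# ---- exact-U enumeration oracle --------------------------------------------

enumerateU <- function(n1, n2) {
    n <- n1 + n2
    freq <- numeric(n1 * n2 + 1)
    sel <- utils::combn(n, n1)
    for (k in seq_len(ncol(sel))) {
        u <- sum(sel[, k]) - n1 * (n1 + 1) / 2
        freq[u + 1] <- freq[u + 1] + 1
    }
    freq
}
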
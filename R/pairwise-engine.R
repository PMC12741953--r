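# All-pairs engine: pair enumeration, on-the-fly pairwise deletion,
# per-feature work units, thread scheduling and bundle assembly.

.testRegistry <- list(
    pearson  = list(homogeneous = TRUE,  xKinds = "continuous",
                    effects = "r2"),
    spearman = list(homogeneous = TRUE,  xKinds = "continuous",
                    effects = "rho"),
    chi2     = list(homogeneous = TRUE,  xKinds = c("categorical", "dichotomous"),
                    effects = c("phi", "cramers_v")),
    ttest    = list(homogeneous = FALSE, xKinds = "dichotomous",
                    effects = "cohens_d"),
    mwu      = list(homogeneous = FALSE, xKinds = "dichotomous",
                    effects = "pearson_r"),
    anova    = list(homogeneous = FALSE, xKinds = c("categorical", "dichotomous"),
                    effects = "partial_eta2"),
    kruskal  = list(homogeneous = FALSE, xKinds = c("categorical", "dichotomous"),
                    effects = "eta2"))

.pAdjustNames <- c(p_bonferroni = "bonferroni",
                   p_benjamini_hochberg = "benjamini_hochberg",
                   p_benjamini_yekutieli = "benjamini_yekutieli")

#' Valid output matrices for a test
#'
#' @param test one of `"pearson"`, `"spearman"`, `"chi2"`, `"ttest"`,
#'   `"mwu"`, `"anova"`, `"kruskal"`.
#' @return character vector of the result names [runPairwise()] accepts for
#'   this test (statistic, unadjusted and adjusted p-values, and the test's
#'   effect sizes).
#' @examples
#' availableOutputs("chi2")
#' @export
availableOutputs <- function(test) {
    test <- match.arg(test, names(.testRegistry))
    c("statistic", "p_unadjusted", names(.pAdjustNames),
      .testRegistry[[test]]$effects)
}

#' Extract the jointly observed entries of a feature pair
#'
#' Pairwise deletion for one pair: keeps exactly the sample positions where
#' both features are non-missing, in the original sample order.  The result
#' may be empty.
#'
#' @param g,h numeric feature vectors of equal length.
#' @param naValue missing-value sentinel (see [isMissing()]).
#' @return a list with `g`, `h` (the retained paired values) and `n`.
#' @examples
#' jointObserved(c(1, NaN, 3, 4), c(NaN, 2, 5, 6))  # pairs (3,5), (4,6)
#' @export
jointObserved <- function(g, h, naValue = NaN) {
    if (length(g) != length(h))
        stop("'g' and 'h' must have equal length")
    keep <- !.missingMask(g, naValue) & !.missingMask(h, naValue)
    list(g = g[keep], h = h[keep], n = sum(keep))
}

#' Presort the features of a continuous matrix
#'
#' Sorts each feature's non-missing values once so that rank-based tests
#' (Spearman, Mann-Whitney U, Kruskal-Wallis) can re-rank any jointly
#' observed subset in a single linear scan per pair instead of re-sorting.
#'
#' @param x a continuous [MixedMatrix].
#' @return a list with one integer vector per feature: the sample indices
#'   of the non-missing entries, in ascending order of their values.
#' @examples
#' m <- MixedMatrix(matrix(c(3, 1, 2), 1, 3))
#' presortFeatures(m)[[1]]  # 2 3 1
#' @export
presortFeatures <- function(x) {
    stopifnot(is(x, "MixedMatrix"))
    v <- x@values
    W <- !.missingMask(v, x@naValue)
    lapply(seq_len(nrow(v)), function(f) {
        idx <- which(unname(W[f, ]))
        idx[order(v[f, idx])]
    })
}

# Tie-averaged ranks of the entries of `v` selected by logical mask `keep`,
# using the feature's presorted order `ord`; aligned with which(keep).
# Equals rankWithTies(v[keep]) but runs in one linear scan.
.subsetRanks <- function(v, ord, keep) {
    o <- ord[keep[ord]]
    m <- length(o)
    if (m == 0L)
        return(numeric(0L))
    vo <- v[o]
    run <- cumsum(c(TRUE, vo[-1L] != vo[-m]))
    rk <- ave(seq_len(m), run)
    tmp <- numeric(length(v))
    tmp[o] <- rk
    tmp[keep]
}

# lapply that optionally fans out over forked workers; results are
# scheduling-independent because each element is computed in isolation.
.papply <- function(X, FUN, threads) {
    if (threads <= 1L || .Platform$OS.type != "unix" || length(X) < 2L)
        return(lapply(X, FUN))
    res <- parallel::mclapply(X, FUN, mc.cores = threads,
                              mc.preschedule = TRUE)
    bad <- vapply(res, inherits, logical(1L), what = "try-error")
    if (any(bad))
        stop("worker error: ", attr(res[[which(bad)[1L]]], "condition")$message)
    res
}

# observed-category label sets and per-sample label codes of a
# categorical/dichotomous matrix
.categoryCodes <- function(x) {
    v <- x@values
    W <- !.missingMask(v, x@naValue)
    labs <- lapply(seq_len(nrow(v)), function(f) sort(unique(v[f, W[f, ]])))
    code <- lapply(seq_len(nrow(v)), function(f) {
        cf <- match(v[f, ], labs[[f]])
        cf[!W[f, ]] <- NA_integer_
        cf
    })
    list(labs = labs, code = code, W = W)
}

## ---- homogeneous sweeps ---------------------------------------------------

# Pearson: per-feature vectorized sweep.  Sums over the joint mask are
# masked matrix-vector products; features are pre-centered by their overall
# observed mean (r is shift-invariant) for numerical stability.
.pearsonAllPairs <- function(x, threads) {
    X <- x@values
    W <- !.missingMask(X, x@naValue)
    nf <- nrow(X)
    Wn <- matrix(0, nf, ncol(X))
    Wn[W] <- 1
    X0 <- X
    X0[!W] <- 0
    nObs <- rowSums(Wn)
    ctr <- ifelse(nObs > 0, rowSums(X0) / pmax(nObs, 1), 0)
    Xc <- (X0 - ctr) * Wn
    X2 <- Xc * Xc
    worker <- function(i) {
        wi <- Wn[i, ]
        xi <- Xc[i, ]
        n   <- as.vector(Wn %*% wi)
        Sj  <- as.vector(Xc %*% wi)
        Sjj <- as.vector(X2 %*% wi)
        Si  <- as.vector(Wn %*% xi)
        Sii <- as.vector(Wn %*% (xi * xi))
        Sij <- as.vector(Xc %*% xi)
        vx <- Si * 0 + NaN
        r <- p <- rep(NaN, nf)
        pos <- n > 0
        cv <- vy <- vx
        vx[pos] <- Sii[pos] - Si[pos]^2 / n[pos]
        vy[pos] <- Sjj[pos] - Sj[pos]^2 / n[pos]
        cv[pos] <- Sij[pos] - Si[pos] * Sj[pos] / n[pos]
        ok <- pos & n >= 2 & vx > 0 & vy > 0
        r[ok] <- pmin(1, pmax(-1, cv[ok] / sqrt(vx[ok] * vy[ok])))
        pok <- ok & n >= 3
        a <- n / 2 - 1
        p[pok] <- pmin(1, 2 * pbeta((1 - abs(r[pok])) / 2, a[pok], a[pok]))
        if (i > 1L) {
            r[seq_len(i - 1L)] <- NA_real_
            p[seq_len(i - 1L)] <- NA_real_
        }
        list(statistic = r, p = p, r2 = r * r)
    }
    rows <- .papply(seq_len(nf), worker, threads)
    .assembleHomogeneous(rows, c("statistic", "p", "r2"), featureNames(x))
}

.spearmanAllPairs <- function(x, threads) {
    X <- x@values
    W <- !.missingMask(X, x@naValue)
    nf <- nrow(X)
    ords <- presortFeatures(x)
    worker <- function(i) {
        wi <- W[i, ]
        stat <- p <- rep(NA_real_, nf)
        for (j in i:nf) {
            keep <- wi & W[j, ]
            cc <- .spearmanFromRanks(.subsetRanks(X[i, ], ords[[i]], keep),
                                     .subsetRanks(X[j, ], ords[[j]], keep))
            stat[j] <- cc[["rho"]]
            p[j] <- cc[["p"]]
        }
        list(statistic = stat, p = p, rho = stat)
    }
    rows <- .papply(seq_len(nf), worker, threads)
    .assembleHomogeneous(rows, c("statistic", "p", "rho"), featureNames(x))
}

.chi2AllPairs <- function(x, threads) {
    cat <- .categoryCodes(x)
    nf <- nFeatures(x)
    worker <- function(i) {
        wi <- cat$W[i, ]
        ki <- length(cat$labs[[i]])
        ci <- cat$code[[i]]
        stat <- p <- phi <- v <- rep(NA_real_, nf)
        for (j in i:nf) {
            kj <- length(cat$labs[[j]])
            if (ki == 0L || kj == 0L) {
                stat[j] <- p[j] <- phi[j] <- v[j] <- NaN
                next
            }
            keep <- wi & cat$W[j, ]
            tab <- matrix(tabulate((ci[keep] - 1L) * kj + cat$code[[j]][keep],
                                   nbins = ki * kj),
                          ki, kj, byrow = TRUE)
            cc <- .chi2Cells(tab)
            stat[j] <- cc[["statistic"]]
            p[j] <- cc[["p"]]
            phi[j] <- cc[["phi"]]
            v[j] <- cc[["cramers_v"]]
        }
        list(statistic = stat, p = p, phi = phi, cramers_v = v)
    }
    rows <- .papply(seq_len(nf), worker, threads)
    .assembleHomogeneous(rows, c("statistic", "p", "phi", "cramers_v"),
                         featureNames(x))
}

# rows: list over i of lists of length-F vectors with entries j >= i filled;
# mirror the upper triangle (each unordered pair computed once).
.assembleHomogeneous <- function(rows, fields, fn) {
    out <- lapply(fields, function(f) {
        m <- do.call(rbind, lapply(rows, `[[`, f))
        lt <- lower.tri(m)
        m[lt] <- t(m)[lt]
        dimnames(m) <- list(fn, fn)
        m
    })
    names(out) <- fields
    out
}

## ---- mixed sweeps ---------------------------------------------------------

# Work unit: one continuous feature, presorted once (rank-based tests) and
# swept against all grouping features.
.mixedAllPairs <- function(test, x, y, threads, variant, mode, continuity) {
    cat <- .categoryCodes(x)
    B <- y@values
    WB <- !.missingMask(B, y@naValue)
    fc <- nFeatures(x)
    fq <- nFeatures(y)
    rankBased <- test %in% c("mwu", "kruskal")
    ords <- if (rankBased) presortFeatures(y) else NULL
    effName <- .testRegistry[[test]]$effects
    worker <- function(q) {
        wq <- WB[q, ]
        vq <- B[q, ]
        ordq <- if (rankBased) ords[[q]] else NULL
        cache <- if (test == "mwu") new.env(parent = emptyenv()) else NULL
        stat <- p <- eff <- rep(NaN, fc)
        for (i in seq_len(fc)) {
            k <- length(cat$labs[[i]])
            if (k == 0L)
                next
            keep <- wq & cat$W[i, ]
            ga <- cat$code[[i]][keep]
            v <- if (rankBased) .subsetRanks(vq, ordq, keep) else vq[keep]
            cc <- switch(test,
                ttest = {
                    if (k < 2L) c(statistic = NaN, p = NaN, cohens_d = NaN)
                    else .ttestCore(v[ga == 1L], v[ga == 2L], variant)
                },
                anova = .anovaCore(split(v, factor(ga, levels = seq_len(k)))),
                mwu = {
                    if (k < 2L) c(statistic = NaN, p = NaN, pearson_r = NaN)
                    else .mwuFromRanks(v, ga, mode, continuity, cache)
                },
                kruskal = .kruskalFromRanks(v, ga, k))
            stat[i] <- cc[["statistic"]]
            p[i] <- cc[["p"]]
            eff[i] <- cc[[effName]]
        }
        list(statistic = stat, p = p, eff = eff)
    }
    cols <- .papply(seq_len(fq), worker, threads)
    dn <- list(featureNames(x), featureNames(y))
    out <- list(
        statistic = do.call(cbind, lapply(cols, `[[`, "statistic")),
        p = do.call(cbind, lapply(cols, `[[`, "p")))
    out[[effName]] <- do.call(cbind, lapply(cols, `[[`, "eff"))
    out <- lapply(out, function(m) { dimnames(m) <- dn; m })
    out
}

## ---- driver ---------------------------------------------------------------

#' Run one statistical test on all feature pairs
#'
#' The workhorse of the package.  Enumerates all feature pairs of one
#' matrix (homogeneous tests: Pearson, Spearman, chi-squared; each
#' unordered pair computed once and mirrored) or of two matrices sharing
#' the sample dimension (mixed tests: t-test and Mann-Whitney U for
#' dichotomous-vs-continuous, ANOVA and Kruskal-Wallis for
#' categorical-vs-continuous), performs pairwise missing-value deletion
#' inside the statistic computation for every pair, and assembles the
#' requested result matrices into a [ResultBundle].
#'
#' The work unit distributed across threads is one feature: for rank-based
#' tests each worker sorts its continuous feature once and re-ranks every
#' jointly observed subset in a linear scan.  Results are identical for
#' every value of `threads` (no scheduling-dependent state).
#'
#' For homogeneous tests the diagonal of the statistic and unadjusted-p
#' matrices holds the self-test of each feature (e.g. Pearson r = 1);
#' adjusted p-value matrices have `NaN` on the diagonal because self-tests
#' are not counted as performed tests (see [adjustMatrix()]).
#'
#' @param test one of `"pearson"`, `"spearman"`, `"chi2"`, `"ttest"`,
#'   `"mwu"`, `"anova"`, `"kruskal"`.
#' @param x a [MixedMatrix]: continuous for the correlations, categorical
#'   (or dichotomous) for `"chi2"`, dichotomous for `"ttest"`/`"mwu"`,
#'   categorical or dichotomous for `"anova"`/`"kruskal"`.
#' @param y for mixed tests, the continuous [MixedMatrix] sharing the
#'   sample dimension with `x`; must be `NULL` for homogeneous tests.
#' @param threads number of forked worker processes (>= 1).
#' @param outputs result matrices to return; see [availableOutputs()].
#'   Defaults to statistic plus unadjusted p-values.
#' @param variant t-test flavor, `"student"` (default) or `"welch"`.
#' @param mode Mann-Whitney p-value mode, `"auto"` (default), `"exact"`, or
#'   `"asymptotic"`; see [mwuPair()].
#' @param continuity continuity correction for the asymptotic Mann-Whitney
#'   z (default `TRUE`).
#' @return a [ResultBundle].
#' @examples
#' m <- simulateMatrix(5, 40, kind = "continuous", seed = 1)
#' m <- injectMissing(m, 0.2, "MCAR", seed = 2)
#' b <- runPairwise("pearson", m,
#'                  outputs = c("statistic", "p_unadjusted", "p_benjamini_hochberg"))
#' b[["statistic"]][1:3, 1:3]
#' @export
runPairwise <- function(test, x, y = NULL, threads = 1L,
                        outputs = c("statistic", "p_unadjusted"),
                        variant = c("student", "welch"),
                        mode = c("auto", "exact", "asymptotic"),
                        continuity = TRUE) {
    test <- match.arg(test, names(.testRegistry))
    variant <- match.arg(variant)
    mode <- match.arg(mode)
    if (!is(x, "MixedMatrix"))
        stop("'x' must be a MixedMatrix")
    reg <- .testRegistry[[test]]
    if (!featureKind(x) %in% reg$xKinds)
        stop("test '", test, "' requires 'x' of kind ",
             paste(reg$xKinds, collapse = " or "),
             ", got '", featureKind(x), "'")
    if (reg$homogeneous) {
        if (!is.null(y))
            stop("test '", test, "' is homogeneous and uses a single matrix")
    } else {
        if (!is(y, "MixedMatrix") || featureKind(y) != "continuous")
            stop("test '", test, "' requires a continuous MixedMatrix 'y'")
        if (nSamples(x) != nSamples(y))
            stop("'x' and 'y' must share the sample dimension (",
                 nSamples(x), " vs ", nSamples(y), ")")
    }
    threads <- max(1L, as.integer(threads)[1L])
    valid <- availableOutputs(test)
    if (length(outputs) == 0L)
        stop("'outputs' must name at least one result; valid: ",
             paste(valid, collapse = ", "))
    bad <- setdiff(outputs, valid)
    if (length(bad))
        stop("invalid output(s) for test '", test, "': ",
             paste(bad, collapse = ", "),
             "; valid: ", paste(valid, collapse = ", "))
    cells <- switch(test,
        pearson = .pearsonAllPairs(x, threads),
        spearman = .spearmanAllPairs(x, threads),
        chi2 = .chi2AllPairs(x, threads),
        .mixedAllPairs(test, x, y, threads, variant, mode, continuity))
    res <- lapply(setNames(outputs, outputs), function(nm) {
        if (nm == "statistic") cells$statistic
        else if (nm == "p_unadjusted") cells$p
        else if (nm %in% names(.pAdjustNames))
            adjustMatrix(cells$p, reg$homogeneous, .pAdjustNames[[nm]])
        else cells[[nm]]
    })
    new("ResultBundle", results = res, test = test,
        homogeneous = reg$homogeneous)
}
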
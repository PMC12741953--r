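# Mann-Whitney U (exact via dynamic programming, or asymptotic with tie
# correction) and Kruskal-Wallis H with tie correction.

# run lengths of equal values among the ranks (tie group sizes)
.tieLengths <- function(r) {
    if (length(r) == 0L) return(integer(0L))
    s <- sort(r)
    rle(s)$lengths
}

#' Exact null distribution of the Mann-Whitney U statistic
#'
#' Builds, by dynamic programming, the frequency table of the U statistic
#' over all `choose(n1 + n2, n1)` equally likely assignments of tie-free
#' ranks to the first group, using the counting recurrence
#' `f(n1, n2, u) = f(n1 - 1, n2, u - n2) + f(n1, n2 - 1, u)` with
#' `f(0, n2, 0) = f(n1, 0, 0) = 1`.  Counts are exact in double precision
#' for every feasible size accepted by `maxProduct`.
#'
#' @param n1,n2 group sizes (each at least 1).
#' @param maxProduct refuse sizes with `n1 * n2` beyond this bound (the DP
#'   table grows quadratically in it); use the asymptotic mode instead.
#' @return a list with `n1`, `n2`, and `freq`, a numeric vector of length
#'   `n1 * n2 + 1` where `freq[u + 1]` counts arrangements with `U = u`.
#' @examples
#' mwuExactDistribution(2, 2)$freq  # 1 1 2 1 1, summing to choose(4, 2)
#' @export
mwuExactDistribution <- function(n1, n2, maxProduct = 10000L) {
    n1 <- as.integer(n1)
    n2 <- as.integer(n2)
    if (n1 < 1L || n2 < 1L)
        stop("'n1' and 'n2' must be at least 1")
    if (as.double(n1) * n2 > maxProduct)
        stop("n1 * n2 = ", n1 * n2, " exceeds maxProduct = ", maxProduct,
             "; the exact distribution is infeasible, use the asymptotic mode")
    U <- n1 * n2
    # f[j + 1, u + 1] = number of arrangements for groups (i, j) with U = u
    f <- matrix(0, n2 + 1L, U + 1L)
    f[, 1L] <- 1          # i = 0: only U = 0
    for (i in seq_len(n1)) {
        g <- matrix(0, n2 + 1L, U + 1L)
        g[1L, 1L] <- 1    # j = 0: only U = 0
        for (j in seq_len(n2)) {
            shifted <- c(rep(0, j), f[j + 1L, seq_len(U + 1L - j)])
            g[j + 1L, ] <- shifted + g[j, ]
        }
        f <- g
    }
    list(n1 = n1, n2 = n2, freq = f[n2 + 1L, ])
}

# Core MWU computation from tie-averaged joint ranks.
# r: ranks of the pooled values; ga: group codes (1 = label 0, 2 = label 1).
.mwuFromRanks <- function(r, ga, mode, continuity = TRUE, cache = NULL,
                          exactBound = 10000L) {
    n1 <- sum(ga == 1L)
    n2 <- sum(ga == 2L)
    if (n1 == 0L || n2 == 0L)
        return(c(statistic = NaN, p = NaN, pearson_r = NaN))
    n <- n1 + n2
    R1 <- sum(r[ga == 1L])
    U1 <- R1 - n1 * (n1 + 1) / 2
    U2 <- n1 * n2 - U1
    lens <- .tieLengths(r)
    tieT <- sum(lens^3 - lens)
    hasTies <- any(lens > 1L)
    s2 <- (n1 * n2 / 12) * ((n + 1) - tieT / (n * (n - 1)))
    if (s2 > 0) {
        d <- U1 - n1 * n2 / 2
        cc <- if (continuity) 0.5 * sign(d) else 0
        z <- (d - cc) / sqrt(s2)
        pAsym <- min(1, 2 * pnorm(-abs(z)))
        reff <- abs(z) / sqrt(n)
    } else {
        # every pooled value tied: z is 0/0
        pAsym <- NaN
        reff <- NaN
    }
    useExact <- switch(mode,
        exact = TRUE,
        asymptotic = FALSE,
        auto = !hasTies && min(n1, n2) < 8L)
    if (useExact) {
        if (hasTies)
            stop("exact Mann-Whitney p-values are undefined in the presence ",
                 "of ties; use mode = 'asymptotic'")
        key <- paste0(n1, "_", n2)
        dist <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]]
                else mwuExactDistribution(n1, n2, exactBound)
        if (!is.null(cache)) cache[[key]] <- dist
        um <- as.integer(round(min(U1, U2)))
        p <- min(1, 2 * sum(dist$freq[seq_len(um + 1L)]) / sum(dist$freq))
    } else {
        p <- pAsym
    }
    c(statistic = U1, p = p, pearson_r = reff)
}

#' Mann-Whitney U test for one jointly observed pair
#'
#' The statistic is `U1 = R1 - n1 (n1 + 1) / 2` for the first group (label
#' 0), with `R1` the sum of its tie-averaged joint ranks.  The asymptotic
#' two-sided p-value uses the normal approximation with the usual tie
#' correction of the variance,
#' `sigma^2 = (n1 n2 / 12) ((n + 1) - sum(t^3 - t) / (n (n - 1)))`, and a
#' continuity correction of 0.5 toward the mean (disable with
#' `continuity = FALSE`).  The exact two-sided p-value doubles the smaller
#' tail of the exact null distribution ([mwuExactDistribution()]), clipped
#' at 1; it is only defined for tie-free data and requesting it under ties
#' is an error.  The default `"auto"` mode selects the exact computation
#' when the pair is tie-free and either group has fewer than 8 samples,
#' and the asymptotic one otherwise.  The effect size is the rank-biserial
#' Pearson r, \eqn{|z| / \sqrt{n_1 + n_2}}, always taken from the
#' asymptotic z.
#'
#' An empty group after pairwise deletion makes every output `NaN`.
#'
#' @param x0,x1 continuous values of the two groups (labels 0 and 1) after
#'   pairwise deletion.
#' @param mode `"auto"` (default), `"exact"` or `"asymptotic"`.
#' @param continuity apply the 0.5 continuity correction in the asymptotic
#'   z (default `TRUE`).
#' @param exactBound passed to [mwuExactDistribution()].
#' @return a list with `statistic` (U of group 0), `p`, `effects`
#'   (`pearson_r`), `n`.
#' @examples
#' mwuPair(c(1, 2), c(3, 4), mode = "exact")$p  # 2/6 = 1/3
#' @export
mwuPair <- function(x0, x1, mode = c("auto", "exact", "asymptotic"),
                    continuity = TRUE, exactBound = 10000L) {
    mode <- match.arg(mode)
    n1 <- length(x0)
    n2 <- length(x1)
    if (n1 == 0L || n2 == 0L)
        return(list(statistic = NaN, p = NaN,
                    effects = c(pearson_r = NaN), n = n1 + n2))
    r <- rankWithTies(c(x0, x1))
    ga <- rep(1:2, c(n1, n2))
    cc <- .mwuFromRanks(r, ga, mode, continuity, cache = NULL,
                        exactBound = exactBound)
    list(statistic = unname(cc["statistic"]), p = unname(cc["p"]),
         effects = c(pearson_r = unname(cc["pearson_r"])), n = n1 + n2)
}

# Core Kruskal-Wallis computation from tie-averaged pooled ranks.
.kruskalFromRanks <- function(r, ga, k) {
    nk <- tabulate(ga, k)
    if (k < 2L || any(nk == 0L))
        return(c(statistic = NaN, p = NaN, eta2 = NaN))
    n <- length(r)
    lens <- .tieLengths(r)
    tieT <- sum(lens^3 - lens)
    Ct <- 1 - tieT / (n^3 - n)
    if (Ct <= 0)
        return(c(statistic = NaN, p = NaN, eta2 = NaN))
    Rk <- as.vector(rowsum(r, ga))
    H <- (12 / (n * (n + 1)) * sum(Rk^2 / nk) - 3 * (n + 1)) / Ct
    p <- pchisq(H, k - 1, lower.tail = FALSE)
    eta2 <- if (n <= k) NaN else (H - k + 1) / (n - k)
    c(statistic = H, p = p, eta2 = eta2)
}

#' Kruskal-Wallis rank test for one jointly observed pair
#'
#' Computes the tie-corrected H statistic
#' `H = (12 / (n (n + 1)) sum(R_k^2 / n_k) - 3 (n + 1)) / C` with
#' `C = 1 - sum(t^3 - t) / (n^3 - n)` over tie groups, the two-sided
#' p-value from the chi-squared survival function at `k - 1` degrees of
#' freedom, and the effect size `eta^2 = (H - k + 1) / (n - k)`.
#'
#' Degenerate contracts: an empty group (category emptied by pairwise
#' deletion) yields all-`NaN`; `eta^2` is `NaN` when `n <= k`; if every
#' pooled value is tied (`C = 0`), H and p are `NaN`.
#'
#' @param groups list of numeric vectors, one per category (ascending label
#'   order), after pairwise deletion.
#' @return a list with `statistic` (H), `p`, `effects` (`eta2`), `n`.
#' @examples
#' kruskalPair(list(c(1, 2, 3), c(1, 2, 3)))$statistic  # 0
#' @export
kruskalPair <- function(groups) {
    stopifnot(is.list(groups))
    k <- length(groups)
    nk <- lengths(groups)
    if (k < 2L || any(nk == 0L))
        return(list(statistic = NaN, p = NaN, effects = c(eta2 = NaN),
                    n = sum(nk)))
    pooled <- unlist(groups, use.names = FALSE)
    r <- rankWithTies(pooled)
    ga <- rep(seq_len(k), nk)
    cc <- .kruskalFromRanks(r, ga, k)
    list(statistic = unname(cc["statistic"]), p = unname(cc["p"]),
         effects = c(eta2 = unname(cc["eta2"])), n = sum(nk))
}
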
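# Pearson and Spearman correlation on jointly observed pairs.
#
# Degenerate contracts (all produce NaN fields, never errors):
#   n <= 1            -> coefficient and p undefined
#   n == 2            -> coefficient defined (+-1), p undefined
#   zero variance     -> coefficient and p undefined

.pearsonCore <- function(x, y) {
    n <- length(x)
    if (n <= 1L)
        return(c(r = NaN, r2 = NaN, p = NaN))
    xc <- x - mean(x)
    yc <- y - mean(y)
    vx <- sum(xc * xc)
    vy <- sum(yc * yc)
    if (vx <= 0 || vy <= 0)
        return(c(r = NaN, r2 = NaN, p = NaN))
    r <- max(-1, min(1, sum(xc * yc) / sqrt(vx * vy)))
    if (n == 2L)
        return(c(r = r, r2 = r * r, p = NaN))
    a <- n / 2 - 1
    p <- min(1, 2 * pbeta((1 - abs(r)) / 2, a, a))
    c(r = r, r2 = r * r, p = p)
}

.spearmanFromRanks <- function(ri, rj) {
    n <- length(ri)
    if (n <= 1L)
        return(c(rho = NaN, p = NaN))
    ri <- ri - mean(ri)
    rj <- rj - mean(rj)
    vx <- sum(ri * ri)
    vy <- sum(rj * rj)
    if (vx <= 0 || vy <= 0)
        return(c(rho = NaN, p = NaN))
    rho <- max(-1, min(1, sum(ri * rj) / sqrt(vx * vy)))
    if (n == 2L)
        return(c(rho = rho, p = NaN))
    p <- if (abs(rho) >= 1) 0 else {
        tt <- rho * sqrt((n - 2) / (1 - rho * rho))
        min(1, 2 * pt(-abs(tt), n - 2))
    }
    c(rho = rho, p = p)
}

#' Tie-averaged ranks
#'
#' Ranks a fully observed numeric vector, assigning tied values the mean of
#' the rank positions they occupy (so rank sums always equal `n(n+1)/2`).
#' A thin, named wrapper around [base::rank()] with
#' `ties.method = "average"`, exported because every rank-based test in the
#' package is defined in terms of this ranking.
#'
#' @param x numeric vector without missing values.
#' @return numeric vector of 1-based, tie-averaged ranks.
#' @examples
#' rankWithTies(c(10, 20, 20, 30))  # 1 2.5 2.5 4
#' @export
rankWithTies <- function(x) {
    if (anyNA(x))
        stop("'x' must not contain missing values; apply jointObserved() first")
    rank(x, ties.method = "average")
}

#' Pearson correlation for one jointly observed feature pair
#'
#' Computes the sample Pearson correlation coefficient of two equal-length
#' vectors (already reduced to their jointly observed entries, see
#' [jointObserved()]) together with a two-sided p-value from the symmetric
#' beta distribution with both shape parameters `n/2 - 1`, and the
#' `r2` effect size.  With fewer than 2 observations, or zero variance in
#' either vector, the undefined fields are `NaN`; with exactly 2
#' observations the coefficient is defined but the p-value is not.
#'
#' @param x,y numeric vectors of equal length, no missing entries.
#' @return a list with elements `statistic` (r), `p`, `effects`
#'   (named vector with `r2`), and `n`.
#' @examples
#' pairstat::pearsonPair(c(0, 1, 2), c(0, 1, 2))  # r = 1, p = 0
#' @export
pearsonPair <- function(x, y) {
    if (length(x) != length(y))
        stop("'x' and 'y' must have equal length")
    cc <- .pearsonCore(x, y)
    list(statistic = unname(cc["r"]), p = unname(cc["p"]),
         effects = c(r2 = unname(cc["r2"])), n = length(x))
}

#' Spearman rank correlation for one jointly observed feature pair
#'
#' Computes rho as the Pearson correlation of tie-averaged ranks (valid
#' under ties, unlike the classical `6 * sum(d^2)` shortcut) with a
#' two-sided p-value from the t-distribution with `n - 2` degrees of
#' freedom via `t = rho * sqrt((n - 2) / (1 - rho^2))`; `|rho| = 1` yields
#' `p = 0`.  Degenerate inputs follow the same NaN contract as
#' [pearsonPair()] (p additionally undefined for `n <= 2`).
#'
#' @param x,y numeric vectors of equal length, no missing entries.
#' @return a list with elements `statistic` (rho), `p`, `effects`
#'   (named vector with `rho`), and `n`.
#' @examples
#' pairstat::spearmanPair(1:4, c(4, 3, 2, 1))  # rho = -1, p = 0
#' @export
spearmanPair <- function(x, y) {
    if (length(x) != length(y))
        stop("'x' and 'y' must have equal length")
    cc <- if (length(x) == 0L) c(rho = NaN, p = NaN)
          else .spearmanFromRanks(rankWithTies(x), rankWithTies(y))
    list(statistic = unname(cc["rho"]), p = unname(cc["p"]),
         effects = c(rho = unname(cc["rho"])), n = length(x))
}
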
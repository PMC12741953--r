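# Chi-squared test of independence for categorical-categorical pairs.

# tab: R x C contingency table of counts over the *full-feature* category
# sets.  Contract: if a category that exists in the full feature is emptied
# by pairwise deletion, every output is NaN; if a feature has only a single
# category, p and Cramer's V are NaN (the statistic and phi are still 0).
.chi2Cells <- function(tab) {
    n <- sum(tab)
    if (n == 0)
        return(c(statistic = NaN, p = NaN, phi = NaN, cramers_v = NaN))
    rs <- rowSums(tab)
    cs <- colSums(tab)
    if (any(rs == 0) || any(cs == 0))
        return(c(statistic = NaN, p = NaN, phi = NaN, cramers_v = NaN))
    R <- nrow(tab)
    C <- ncol(tab)
    E <- outer(rs, cs) / n
    stat <- sum((tab - E)^2 / E)
    phi <- sqrt(stat / n)
    if (R == 1L || C == 1L)
        return(c(statistic = stat, p = NaN, phi = phi, cramers_v = NaN))
    p <- pchisq(stat, (R - 1) * (C - 1), lower.tail = FALSE)
    v <- sqrt(stat / (n * (min(R, C) - 1)))
    c(statistic = stat, p = p, phi = phi, cramers_v = v)
}

.buildTable <- function(x, y, labelsX, labelsY) {
    R <- length(labelsX)
    C <- length(labelsY)
    if (R == 0L || C == 0L)
        return(matrix(0, max(R, 1L), max(C, 1L)))
    cx <- match(x, labelsX)
    cy <- match(y, labelsY)
    if (anyNA(cx) || anyNA(cy))
        stop("observed values outside the declared category sets")
    matrix(tabulate((cx - 1L) * C + cy, nbins = R * C), R, C, byrow = TRUE)
}

#' Chi-squared test of independence for one jointly observed pair
#'
#' Builds the contingency table of two label-encoded categorical vectors
#' (already reduced to their jointly observed entries) over the category
#' sets of the *full* features, and computes the chi-squared statistic
#' `sum((O - E)^2 / E)` with expected counts from the table margins, the
#' two-sided p-value from the chi-squared survival function at
#' `(R - 1)(C - 1)` degrees of freedom, and the effect sizes
#' `phi = sqrt(chi2 / n)` and Cramer's `V = sqrt(chi2 / (n (min(R, C) - 1)))`.
#' No continuity correction is applied for 2x2 tables.
#'
#' If any category present in the full feature is emptied by pairwise
#' deletion, every output is `NaN`.  If a feature carries only one category,
#' `p` and Cramer's V are `NaN` (`statistic` and `phi` are 0).
#'
#' @param x,y label-encoded numeric vectors of equal length, no missing
#'   entries.
#' @param labelsX,labelsY the category labels of the full features (default:
#'   the labels observed in `x`, `y` themselves).
#' @return a list with elements `statistic`, `p`, `effects` (named vector
#'   with `phi`, `cramers_v`), and `n`.
#' @examples
#' x <- rep(c(0, 0, 1, 1), each = 10)
#' y <- rep(c(0, 1, 0, 1), each = 10)
#' chi2Pair(x, y)  # independent 2x2 table: statistic 0, p 1
#' @export
chi2Pair <- function(x, y, labelsX = NULL, labelsY = NULL) {
    if (length(x) != length(y))
        stop("'x' and 'y' must have equal length")
    if (is.null(labelsX)) labelsX <- sort(unique(x))
    if (is.null(labelsY)) labelsY <- sort(unique(y))
    tab <- .buildTable(x, y, labelsX, labelsY)
    cc <- .chi2Cells(tab)
    list(statistic = unname(cc["statistic"]), p = unname(cc["p"]),
         effects = c(phi = unname(cc["phi"]),
                     cramers_v = unname(cc["cramers_v"])),
         n = length(x))
}
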
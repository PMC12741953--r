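# Bonferroni, Benjamini-Hochberg and Benjamini-Yekutieli adjustment of
# p-value vectors and all-pairs p-value matrices, with self-test exclusion.

.resolveAdjustMethod <- function(method) {
    key <- tolower(method[1L])
    map <- c(bonferroni = "bonferroni",
             benjamini_hochberg = "BH", bh = "BH",
             benjamini_yekutieli = "BY", by = "BY")
    if (!key %in% names(map))
        stop("unknown adjustment method '", method,
             "'; valid: bonferroni, benjamini_hochberg (bh), ",
             "benjamini_yekutieli (by)")
    unname(map[key])
}

#' Adjust a vector of p-values for multiple testing
#'
#' Applies Bonferroni (`min(1, m p)`), Benjamini--Hochberg (step-up with
#' enforced monotonicity) or Benjamini--Yekutieli (BH inflated by the
#' harmonic sum `c(m) = sum(1/i)`) adjustment, delegating the arithmetic
#' to [stats::p.adjust()].  `NaN`/`NA` entries (degenerate tests) stay
#' `NaN` and are excluded from the effective number of tests `m`, since
#' they were never actually performed.
#'
#' @param p numeric vector of p-values in `[0, 1]`, possibly containing
#'   `NaN`/`NA`.
#' @param method `"bonferroni"`, `"benjamini_hochberg"` (alias `"bh"`), or
#'   `"benjamini_yekutieli"` (alias `"by"`).
#' @return numeric vector of adjusted p-values, `NaN` where the input was
#'   missing, in the input order.
#' @examples
#' adjustPvalues(c(0.01, 0.02, 0.03, 0.04), "bonferroni")
#' adjustPvalues(c(0.01, NaN), "bonferroni")  # m = 1: 0.01, NaN
#' @export
adjustPvalues <- function(p,
        method = c("bonferroni", "benjamini_hochberg", "benjamini_yekutieli")) {
    if (!is.numeric(p))
        stop("'p' must be numeric")
    method <- .resolveAdjustMethod(method)
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1))
        stop("p-values must lie in [0, 1]")
    out <- rep(NaN, length(p))
    if (any(ok))
        out[ok] <- p.adjust(p[ok], method = method)
    out
}

#' Adjust an all-pairs p-value matrix for multiple testing
#'
#' For homogeneous (square, symmetric) matrices, each unordered off-diagonal
#' feature pair with a defined p-value counts exactly once toward the
#' effective number of tests; the self-tests on the diagonal are not counted
#' as performed tests and the diagonal of the output is therefore set to
#' `NaN`.  Adjusted values are mirrored back symmetrically.  For mixed
#' (rectangular) matrices, every defined cell counts.
#'
#' @param P numeric p-value matrix (`NaN` allowed).
#' @param homogeneous `TRUE` for a square symmetric all-pairs matrix.
#' @param method see [adjustPvalues()].
#' @return adjusted matrix of the same shape (and dimnames).
#' @examples
#' P <- matrix(0.01, 3, 3)
#' adjustMatrix(P, homogeneous = TRUE, method = "bonferroni")
#' # off-diagonal 0.03 (m = 3 unordered pairs), diagonal NaN
#' @export
adjustMatrix <- function(P, homogeneous,
        method = c("bonferroni", "benjamini_hochberg", "benjamini_yekutieli")) {
    if (!is.matrix(P) || !is.numeric(P))
        stop("'P' must be a numeric matrix")
    if (!homogeneous) {
        return(matrix(adjustPvalues(as.vector(P), method),
                      nrow(P), ncol(P), dimnames = dimnames(P)))
    }
    if (nrow(P) != ncol(P))
        stop("homogeneous p-value matrices must be square")
    if (!isTRUE(all.equal(P, t(P), check.attributes = FALSE)))
        stop("homogeneous p-value matrices must be symmetric (up to NaN)")
    ut <- upper.tri(P)
    out <- matrix(NaN, nrow(P), ncol(P), dimnames = dimnames(P))
    out[ut] <- adjustPvalues(P[ut], method)
    lt <- lower.tri(out)
    out[lt] <- t(out)[lt]
    out
}
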
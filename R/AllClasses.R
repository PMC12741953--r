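#' MixedMatrix: a validated feature-by-sample matrix of one variable kind
#'
#' The central input container.  After construction, rows always index
#' features and columns always index samples, regardless of the orientation
#' of the raw input.  The matrix holds double-precision values; missing
#' entries are marked by a floating-point sentinel (`NaN` by default).  For
#' `kind = "categorical"` every non-missing entry must be a non-negative
#' integer-valued label (label encoding, labels starting at 0); for
#' `kind = "dichotomous"` labels are restricted to `{0, 1}`.
#'
#' @slot values double matrix, features in rows, samples in columns.
#' @slot kind one of `"continuous"`, `"dichotomous"`, `"categorical"`.
#' @slot naValue length-one numeric sentinel marking missing entries.
#'   `NaN`/`NA` entries are always treated as missing; when the sentinel is
#'   finite, entries exactly equal to it are missing as well.
#'
#' @seealso [MixedMatrix()] for the validating constructor, [isMissing()],
#'   [runPairwise()].
#' @aliases MixedMatrix-class
#' @exportClass MixedMatrix
setClass("MixedMatrix",
    slots = c(values = "matrix", kind = "character", naValue = "numeric"))

.missingMask <- function(v, naValue) {
    m <- is.na(v)
    if (length(naValue) == 1L && is.finite(naValue))
        m <- m | (!is.na(v) & v == naValue)
    m
}

.validMixedMatrix <- function(object) {
    v <- object@values
    if (!is.numeric(v))
        return("'values' must be a numeric matrix")
    if (length(dim(v)) != 2L || nrow(v) < 1L || ncol(v) < 1L)
        return("'values' must have at least 1 feature and 1 sample")
    if (length(object@kind) != 1L ||
        !object@kind %in% c("continuous", "dichotomous", "categorical"))
        return("'kind' must be one of 'continuous', 'dichotomous', 'categorical'")
    if (length(object@naValue) != 1L)
        return("'naValue' must be a single numeric value")
    if (object@kind %in% c("dichotomous", "categorical")) {
        miss <- .missingMask(v, object@naValue)
        bad <- !miss & (v < 0 | v != round(v))
        if (object@kind == "dichotomous")
            bad <- bad | (!miss & v > 1)
        if (any(bad)) {
            f <- which(rowSums(bad) > 0L)[1L]
            s <- which(bad[f, ])[1L]
            lab <- rownames(v)[f]
            if (is.null(lab)) lab <- f
            return(sprintf(
                "feature '%s': entry at sample %d (%.6g) is not a valid %s label",
                lab, s, v[f, s],
                if (object@kind == "dichotomous") "{0,1} dichotomous"
                else "non-negative integer category"))
        }
    }
    TRUE
}

setValidity("MixedMatrix", .validMixedMatrix)

#' ResultBundle: named collection of all-pairs result matrices
#'
#' Returned by [runPairwise()].  Holds one matrix per requested output
#' (`statistic`, `p_unadjusted`, adjusted p-values, effect sizes).  For
#' homogeneous tests (Pearson, Spearman, chi-squared) every matrix is
#' features-by-features and symmetric; adjusted p-value matrices carry `NaN`
#' on the diagonal because self-tests do not count as performed hypotheses.
#' For mixed tests, rows index the categorical/dichotomous features and
#' columns the continuous features.
#'
#' @slot results named list of equally sized numeric matrices.
#' @slot test the test that produced the bundle.
#' @slot homogeneous `TRUE` for single-matrix (symmetric) tests.
#'
#' @seealso [runPairwise()], [resultNames()]
#' @name ResultBundle
#' @aliases ResultBundle-class ResultBundle
#' @exportClass ResultBundle
setClass("ResultBundle",
    slots = c(results = "list", test = "character", homogeneous = "logical"))

.validResultBundle <- function(object) {
    r <- object@results
    if (length(r) == 0L)
        return("a ResultBundle must contain at least one result matrix")
    if (is.null(names(r)) || any(!nzchar(names(r))))
        return("all result matrices must be named")
    if (!all(vapply(r, is.matrix, logical(1L))))
        return("all results must be matrices")
    d <- dim(r[[1L]])
    if (!all(vapply(r, function(m) identical(dim(m), d), logical(1L))))
        return("all result matrices must share the same dimensions")
    TRUE
}

setValidity("ResultBundle", .validResultBundle)

setMethod("show", "MixedMatrix", function(object) {
    v <- object@values
    miss <- mean(.missingMask(v, object@naValue))
    cat(sprintf("MixedMatrix: %d %s feature%s x %d sample%s (%.1f%% missing)\n",
        nrow(v), object@kind, if (nrow(v) == 1L) "" else "s",
        ncol(v), if (ncol(v) == 1L) "" else "s", 100 * miss))
    cat("  naValue:", format(object@naValue), "\n")
    fn <- rownames(v)
    if (!is.null(fn))
        cat("  features:", paste(head(fn, 4L), collapse = ", "),
            if (nrow(v) > 4L) "..." else "", "\n")
    invisible(NULL)
})

setMethod("show", "ResultBundle", function(object) {
    d <- dim(object@results[[1L]])
    cat(sprintf("ResultBundle: test '%s' (%s), %d x %d matrices\n",
        object@test,
        if (object@homogeneous) "homogeneous" else "mixed",
        d[1L], d[2L]))
    cat("  results:", paste(names(object@results), collapse = ", "), "\n")
    invisible(NULL)
})
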
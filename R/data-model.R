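#' Construct a validated MixedMatrix
#'
#' Validates and orients a raw numeric matrix into the feature-by-sample
#' layout shared by all pairwise tests.  When `featureAxis = "columns"` the
#' input is transposed, so that downstream code can always assume rows are
#' features.  Label encoding is enforced for categorical input (non-negative
#' integer-valued entries; `{0, 1}` for dichotomous input) on all non-missing
#' entries, and a violation is reported with the offending feature.
#'
#' @param values a two-dimensional numeric matrix (or data frame of numeric
#'   columns).
#' @param kind variable kind of all features in the matrix: `"continuous"`,
#'   `"dichotomous"` or `"categorical"`.
#' @param naValue floating-point sentinel marking missing entries.  `NaN`
#'   (the default) makes every `NaN`/`NA` entry missing; a finite sentinel is
#'   matched by exact equality (and `NaN`/`NA` entries are still treated as
#'   missing).
#' @param featureAxis which input dimension indexes features; `"rows"`
#'   (default) or `"columns"`.
#' @param featureNames,sampleNames optional identifier vectors; defaults are
#'   taken from the input's `dimnames` or generated (`F1..`, `S1..`).
#'
#' @return a [MixedMatrix] object with features in rows.
#'
#' @examples
#' m <- MixedMatrix(rbind(c(0, 1, NaN), c(1, 0, 1)), kind = "dichotomous")
#' nFeatures(m)  # 2
#' nSamples(m)   # 3
#' @export
MixedMatrix <- function(values,
                        kind = c("continuous", "dichotomous", "categorical"),
                        naValue = NaN,
                        featureAxis = c("rows", "columns"),
                        featureNames = NULL, sampleNames = NULL) {
    kind <- match.arg(kind)
    featureAxis <- match.arg(featureAxis)
    if (is.data.frame(values))
        values <- as.matrix(values)
    if (!is.matrix(values) || !is.numeric(values))
        stop("'values' must be a two-dimensional numeric matrix")
    if (featureAxis == "columns")
        values <- t(values)
    if (nrow(values) < 1L || ncol(values) < 1L)
        stop("'values' must have at least 1 feature and 1 sample")
    if (is.null(featureNames))
        featureNames <- rownames(values)
    if (is.null(featureNames))
        featureNames <- paste0("F", seq_len(nrow(values)))
    if (is.null(sampleNames))
        sampleNames <- colnames(values)
    if (is.null(sampleNames))
        sampleNames <- paste0("S", seq_len(ncol(values)))
    if (length(featureNames) != nrow(values))
        stop("'featureNames' must have one entry per feature")
    if (length(sampleNames) != ncol(values))
        stop("'sampleNames' must have one entry per sample")
    storage.mode(values) <- "double"
    dimnames(values) <- list(as.character(featureNames),
                             as.character(sampleNames))
    obj <- new("MixedMatrix", values = values, kind = kind,
               naValue = as.numeric(naValue)[1L])
    validObject(obj)
    obj
}

#' Accessors for MixedMatrix objects
#'
#' `values()` returns the oriented feature-by-sample double matrix;
#' `featureKind()` the declared variable kind; `naValue()` the missing-value
#' sentinel; `nFeatures()`/`nSamples()` the dimensions; `featureNames()` and
#' `sampleNames()` the identifiers.
#'
#' @param x a [MixedMatrix].
#' @param ... ignored.
#' @return see the individual descriptions.
#' @name MixedMatrix-accessors
#' @examples
#' m <- MixedMatrix(matrix(runif(6), 2, 3))
#' dim(values(m))
#' featureKind(m)
NULL

#' @rdname MixedMatrix-accessors
#' @export
setMethod("values", "MixedMatrix", function(x, ...) x@values)

#' @rdname MixedMatrix-accessors
#' @export
setMethod("featureKind", "MixedMatrix", function(x) x@kind)

#' @rdname MixedMatrix-accessors
#' @export
setMethod("naValue", "MixedMatrix", function(x) x@naValue)

#' @rdname MixedMatrix-accessors
#' @export
setMethod("nFeatures", "MixedMatrix", function(x) nrow(x@values))

#' @rdname MixedMatrix-accessors
#' @export
setMethod("nSamples", "MixedMatrix", function(x) ncol(x@values))

#' @rdname MixedMatrix-accessors
#' @export
setMethod("featureNames", "MixedMatrix", function(x) rownames(x@values))

#' @rdname MixedMatrix-accessors
#' @export
setMethod("sampleNames", "MixedMatrix", function(x) colnames(x@values))

#' @rdname MixedMatrix-accessors
#' @export
setMethod("dim", "MixedMatrix", function(x) dim(x@values))

#' Locate missing entries
#'
#' Returns the logical missingness mask of a [MixedMatrix] (or of a plain
#' numeric vector/matrix given an explicit sentinel).  An entry is missing
#' iff it is `NA`/`NaN`, or the sentinel is finite and the entry equals it
#' exactly.
#'
#' @param x a [MixedMatrix], or a numeric vector/matrix.
#' @param naValue sentinel to use for plain numeric input (default `NaN`).
#' @param ... ignored.
#' @return a logical object of the same shape as `x`.
#' @examples
#' isMissing(c(1, NaN, -99), naValue = -99)  # FALSE TRUE TRUE
#' @name isMissing
NULL

#' @rdname isMissing
#' @export
setMethod("isMissing", "MixedMatrix", function(x, ...)
    .missingMask(x@values, x@naValue))

#' @rdname isMissing
#' @export
setMethod("isMissing", "numeric", function(x, naValue = NaN, ...)
    .missingMask(x, naValue))

#' @rdname isMissing
#' @export
setMethod("isMissing", "matrix", function(x, naValue = NaN, ...)
    .missingMask(x, naValue))

#' Accessors for ResultBundle objects
#'
#' `resultNames()` lists the matrices stored in a bundle; `x[[name]]`
#' extracts one result matrix; `as.list()` returns the full named list.
#'
#' @param x a [ResultBundle].
#' @param i result name or index.
#' @param ... ignored.
#' @name ResultBundle-accessors
NULL

#' @rdname ResultBundle-accessors
#' @export
setMethod("resultNames", "ResultBundle", function(x) names(x@results))

#' @rdname ResultBundle-accessors
#' @export
setMethod("[[", "ResultBundle", function(x, i, ...) x@results[[i]])

#' @rdname ResultBundle-accessors
#' @export
setMethod("names", "ResultBundle", function(x) names(x@results))

#' @rdname ResultBundle-accessors
#' @param ... ignored.
#' @export
as.list.ResultBundle <- function(x, ...) x@results
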
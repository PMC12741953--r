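# Benchmark-style mixed-type data simulation with controlled missingness.

#' Simulate a complete mixed-type feature-by-sample matrix
#'
#' Continuous features are drawn i.i.d. uniform on the unit interval
#' `[0, 1]`; categorical features are label-encoded with labels
#' `0 .. nCategories - 1`, and every feature row is guaranteed to contain
#' each label at least once (a shuffled concatenation of one copy of every
#' label with uniform draws for the remaining positions).  Dichotomous
#' features are 2-category categorical features.  The matrix is complete;
#' add missingness with [injectMissing()].
#'
#' @param nFeatures,nSamples matrix dimensions.
#' @param kind `"continuous"`, `"categorical"` or `"dichotomous"`.
#' @param nCategories categories per feature for categorical data
#'   (default 4; forced to 2 for dichotomous).  Requires
#'   `nSamples >= nCategories`.
#' @param naValue missing-value sentinel recorded in the result (no entry
#'   is missing yet).
#' @param seed optional integer seed; identical seeds reproduce the matrix
#'   bit-exactly.
#' @return a complete [MixedMatrix].
#' @examples
#' m <- simulateMatrix(2, 8, kind = "categorical", nCategories = 4, seed = 1)
#' apply(values(m), 1, function(r) all(0:3 %in% r))  # TRUE TRUE
#' @export
simulateMatrix <- function(nFeatures, nSamples,
                           kind = c("continuous", "categorical", "dichotomous"),
                           nCategories = 4L, naValue = NaN, seed = NULL) {
    kind <- match.arg(kind)
    nFeatures <- as.integer(nFeatures)
    nSamples <- as.integer(nSamples)
    if (nFeatures < 1L || nSamples < 1L)
        stop("'nFeatures' and 'nSamples' must be at least 1")
    if (kind == "dichotomous")
        nCategories <- 2L
    nCategories <- as.integer(nCategories)
    if (kind != "continuous") {
        if (nCategories < 2L)
            stop("'nCategories' must be at least 2")
        if (nSamples < nCategories)
            stop("each of the ", nCategories, " categories must appear at ",
                 "least once per feature; need nSamples >= nCategories")
    }
    if (!is.null(seed))
        set.seed(as.integer(seed))
    v <- if (kind == "continuous") {
        matrix(runif(nFeatures * nSamples), nFeatures, nSamples)
    } else {
        labs <- seq_len(nCategories) - 1
        t(vapply(seq_len(nFeatures), function(f)
            sample(c(labs, sample(labs, nSamples - nCategories,
                                  replace = TRUE))),
            numeric(nSamples)))
    }
    MixedMatrix(v, kind = kind, naValue = naValue)
}

# solve the logistic intercept so that mean(plogis(slope * z + b)) = rate
.logisticIntercept <- function(z, slope, rate) {
    f <- function(b) mean(plogis(slope * z + b)) - rate
    uniroot(f, c(-50, 50), tol = 1e-10)$root
}

.standardize <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s <= 0) return(rep(0, length(v)))
    (v - mean(v)) / s
}

#' Inject missing values under MCAR, MAR or MNAR mechanisms
#'
#' MCAR sets exactly `round(rate * nSamples)` entries per feature to the
#' sentinel at uniformly chosen positions.  MAR and MNAR draw per-entry
#' Bernoulli missingness with probability `plogis(slope * z + b)`, where
#' `z` is the standardized value of a driver: for MAR the next feature's
#' (complete, pre-injection) values, for MNAR the entry's own value.  The
#' intercept `b` is solved numerically so the expected missing fraction of
#' each feature equals `rate`.  With positive `slope`, larger driver values
#' are more likely to go missing.
#'
#' For categorical matrices, MCAR feasibility requires that at least as
#' many entries stay observed as there are categories; under the stochastic
#' mechanisms each feature is guaranteed to retain at least one observed
#' entry.
#'
#' @param m a complete [MixedMatrix] (no missing entries).
#' @param rate target missing fraction per feature, in `[0, 1)`.
#' @param mechanism `"MCAR"` (default), `"MAR"` or `"MNAR"`.
#' @param slope logistic slope for MAR/MNAR (default 3).
#' @param seed optional integer seed.
#' @return a [MixedMatrix] with missing entries marked by `naValue(m)`.
#' @examples
#' m <- simulateMatrix(3, 100, seed = 1)
#' mm <- injectMissing(m, 0.1, "MCAR", seed = 2)
#' rowSums(isMissing(mm))  # 10 10 10
#' @export
injectMissing <- function(m, rate, mechanism = c("MCAR", "MAR", "MNAR"),
                          slope = 3, seed = NULL) {
    stopifnot(is(m, "MixedMatrix"))
    mechanism <- match.arg(mechanism)
    if (any(isMissing(m)))
        stop("'m' already contains missing entries")
    if (!is.numeric(rate) || rate < 0 || rate >= 1)
        stop("'rate' must lie in [0, 1)")
    if (rate == 0)
        return(m)
    v <- m@values
    nf <- nrow(v)
    ns <- ncol(v)
    na <- m@naValue
    if (!is.null(seed))
        set.seed(as.integer(seed))
    if (mechanism == "MCAR") {
        k <- round(rate * ns)
        if (featureKind(m) != "continuous") {
            ncat <- max(vapply(seq_len(nf),
                               function(f) length(unique(v[f, ])), numeric(1L)))
            if (ns - k < ncat)
                stop("rate ", rate, " leaves fewer observed entries than ",
                     "categories per feature")
        }
        for (f in seq_len(nf))
            if (k > 0L) v[f, sample.int(ns, k)] <- na
    } else {
        if (mechanism == "MAR" && nf < 2L)
            stop("MAR needs at least 2 features (one acts as driver)")
        v0 <- v  # drivers are the complete, pre-injection values
        for (f in seq_len(nf)) {
            z <- if (mechanism == "MAR")
                .standardize(v0[f %% nf + 1L, ]) else .standardize(v0[f, ])
            b <- .logisticIntercept(z, slope, rate)
            miss <- runif(ns) < plogis(slope * z + b)
            if (all(miss))
                miss[sample.int(ns, 1L)] <- FALSE
            v[f, miss] <- na
        }
    }
    out <- m
    out@values <- v
    out
}
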
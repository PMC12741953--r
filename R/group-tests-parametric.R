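# Two-sample t-test and one-way ANOVA for group comparisons of a continuous
# variable, with Cohen's D and partial eta-squared effect sizes.

.ttestCore <- function(x0, x1, variant) {
    n1 <- length(x0)
    n2 <- length(x1)
    if (n1 < 2L || n2 < 2L || n1 + n2 < 3L)
        return(c(statistic = NaN, p = NaN, cohens_d = NaN))
    m1 <- mean(x0); m2 <- mean(x1)
    v1 <- var(x0);  v2 <- var(x1)
    if (variant == "student") {
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        if (sp2 <= 0)
            return(c(statistic = NaN, p = NaN, cohens_d = NaN))
        tv <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- n1 + n2 - 2
        d <- (m1 - m2) / sqrt(sp2)
    } else {
        if (v1 + v2 <= 0) {
            # Welch statistic degenerates: +-Inf/p=0 when the means differ,
            # 0/0 (all NaN) when they coincide; Cohen's D is never defined.
            if (m1 == m2)
                return(c(statistic = NaN, p = NaN, cohens_d = NaN))
            return(c(statistic = sign(m1 - m2) * Inf, p = 0, cohens_d = NaN))
        }
        se2 <- v1 / n1 + v2 / n2
        tv <- (m1 - m2) / sqrt(se2)
        df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
        d <- (m1 - m2) / sqrt((v1 + v2) / 2)
    }
    p <- min(1, 2 * pt(-abs(tv), df))
    c(statistic = tv, p = p, cohens_d = d)
}

.anovaCore <- function(groups) {
    nk <- lengths(groups)
    k <- length(groups)
    if (k < 2L || any(nk == 0L))
        return(c(statistic = NaN, p = NaN, partial_eta2 = NaN))
    n <- sum(nk)
    if (n - k < 1L)
        return(c(statistic = NaN, p = NaN, partial_eta2 = NaN))
    mk <- vapply(groups, mean, numeric(1L))
    gm <- sum(nk * mk) / n
    ssb <- sum(nk * (mk - gm)^2)
    ssw <- sum(vapply(seq_len(k),
                      function(i) sum((groups[[i]] - mk[i])^2), numeric(1L)))
    if (ssw <= 0) {
        # all within-group variances vanish: infinite F when the group means
        # differ (beyond numerical noise), otherwise undefined
        if (max(mk) - min(mk) > 1e-12)
            return(c(statistic = Inf, p = 0, partial_eta2 = 1))
        return(c(statistic = NaN, p = NaN, partial_eta2 = NaN))
    }
    fv <- (ssb / (k - 1)) / (ssw / (n - k))
    p <- pf(fv, k - 1, n - k, lower.tail = FALSE)
    c(statistic = fv, p = p, partial_eta2 = ssb / (ssb + ssw))
}

#' Two-sample t-test for one jointly observed pair
#'
#' Student's t-test uses the pooled variance
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)` with `n1+n2-2` degrees
#' of freedom and Cohen's `D = (m1-m2)/sp`; Welch's t-test uses unpooled
#' variances with Welch-Satterthwaite degrees of freedom and Cohen's
#' `D = (m1-m2)/sqrt((s1^2+s2^2)/2)`.  Two-sided p-values come from the
#' t-distribution survival function.
#'
#' Degenerate contracts (all yield `NaN`, never errors): fewer than 2
#' samples in either group, or fewer than 3 in total; Student with zero
#' pooled standard deviation; Welch's Cohen's D when both group variances
#' are zero.
#'
#' @param x0,x1 continuous values of the two groups (labels 0 and 1) after
#'   pairwise deletion.  The reported statistic has the sign of
#'   `mean(x0) - mean(x1)`.
#' @param variant `"student"` (default, equal variances) or `"welch"`.
#' @return a list with `statistic` (t), `p`, `effects` (`cohens_d`), `n`.
#' @examples
#' ttestPair(c(1, 2, 3), c(1, 2, 3))  # t = 0, p = 1, D = 0
#' @export
ttestPair <- function(x0, x1, variant = c("student", "welch")) {
    variant <- match.arg(variant)
    cc <- .ttestCore(x0, x1, variant)
    list(statistic = unname(cc["statistic"]), p = unname(cc["p"]),
         effects = c(cohens_d = unname(cc["cohens_d"])),
         n = length(x0) + length(x1))
}

#' One-way analysis of variance for one jointly observed pair
#'
#' Computes `F = (SS_between / (k - 1)) / (SS_within / (n - k))` over the
#' groups induced by a categorical feature, the two-sided p-value from the
#' F-distribution survival function at `(k - 1, n - k)` degrees of freedom,
#' and `partial eta^2 = SS_between / (SS_between + SS_within)`.
#'
#' Degenerate contracts: any empty group (a category emptied by pairwise
#' deletion) yields all-`NaN`; if every within-group variance is zero the
#' result is `F = Inf`, `p = 0` when the group means differ and all-`NaN`
#' when they coincide (equality tested within an absolute tolerance of
#' 1e-12).
#'
#' @param groups list of numeric vectors, one per category (ascending label
#'   order), after pairwise deletion.
#' @return a list with `statistic` (F), `p`, `effects` (`partial_eta2`),
#'   `n`.
#' @examples
#' anovaPair(list(c(1, 1), c(2, 2)))  # zero within-variance: F = Inf, p = 0
#' @export
anovaPair <- function(groups) {
    stopifnot(is.list(groups))
    cc <- .anovaCore(groups)
    list(statistic = unname(cc["statistic"]), p = unname(cc["p"]),
         effects = c(partial_eta2 = unname(cc["partial_eta2"])),
         n = sum(lengths(groups)))
}
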
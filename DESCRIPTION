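Package: pairstat
Title: Parallel All-Pairs Association Testing for Mixed-Type Data with
    Pairwise Missing-Value Removal
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes all pairwise statistical associations between the
    features of large mixed-type (continuous, dichotomous, categorical)
    data matrices, removing missing values pairwise on the fly inside
    each test instead of by complete-case deletion or imputation.
    Implements Pearson and Spearman correlation, the chi-squared test of
    independence, Student and Welch two-sample t-tests, the Mann-Whitney
    U test (exact null distribution via dynamic programming, or
    asymptotic with tie correction), one-way analysis of variance, and
    the Kruskal-Wallis test.  Each test returns feature-by-feature
    matrices of test statistics, two-sided p-values, multiple-testing
    adjusted p-values (Bonferroni, Benjamini-Hochberg,
    Benjamini-Yekutieli) and effect sizes, computed deterministically
    across any number of worker threads.  Also provides a mixed-type
    cohort-style data simulator with MCAR, MAR and MNAR missingness
    mechanisms, delimited-matrix input/output, and a command-line entry
    point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    parallel,
    data.table,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
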
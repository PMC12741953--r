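# pairstat

All-pairs statistical association testing for large mixed-type data
matrices, with missing values removed **pairwise, on the fly** inside
every test.

## The problem

Cohort-style biomedical datasets combine continuous measurements,
dichotomous traits and label-encoded categorical variables across
thousands of features, and almost every feature has missing entries.
Analyses that need *all* pairwise associations — association networks,
interactive data explorers, exploratory screens — cannot afford
complete-case analysis (too much data lost) or imputation (results depend
on the imputation model).  pairstat instead computes, for every feature
pair `(g, h)`, the statistic on the jointly observed sample set

```
I(g, h) = { (g_i, h_i) : g_i != m  and  h_i != m }
```

where `m` is a user-chosen floating-point missing sentinel (`NaN` by
default).

Seven tests cover every combination of variable kinds, each with
two-sided p-values, Bonferroni / Benjamini–Hochberg / Benjamini–Yekutieli
adjusted p-values, and the customary effect sizes:

| test | input kinds | statistic | effect size |
|---|---|---|---|
| `pearson` | continuous–continuous | r | r² |
| `spearman` | continuous–continuous | ρ | ρ |
| `chi2` | categorical–categorical | χ² | φ, Cramér's V |
| `ttest` (Student/Welch) | dichotomous vs continuous | t | Cohen's D |
| `mwu` (exact/asymptotic/auto) | dichotomous vs continuous | U | Pearson r from z |
| `anova` | categorical vs continuous | F | partial η² |
| `kruskal` | categorical vs continuous | H (tie-corrected) | η² |

The exact Mann–Whitney null distribution is built by a dynamic-programming
counting recurrence; the asymptotic mode uses the tie-corrected normal
approximation with continuity correction.  Degenerate pairs (too few
jointly observed samples, emptied categories, zero variance, …) return
`NaN` results instead of failing, so all-pairs runs always complete.
Results are bit-identical for any number of worker threads.

## Worked example

```r
library(pairstat)

x <- simulateMatrix(6, 120, kind = "continuous", seed = 11)  # uniform [0,1]
x <- injectMissing(x, 0.15, "MCAR", seed = 12)               # 15% per feature
b <- runPairwise("pearson", x,
                 outputs = c("statistic", "p_unadjusted",
                             "p_benjamini_hochberg"))
b
#> ResultBundle: test 'pearson' (homogeneous), 6 x 6 matrices
#>   results: statistic, p_unadjusted, p_benjamini_hochberg

round(b[["statistic"]], 3)
#>        F1     F2     F3     F4     F5     F6
#> F1  1.000 -0.010 -0.005  0.040  0.246  0.112
#> F2 -0.010  1.000  0.097  0.119 -0.075  0.074
#> F3 -0.005  0.097  1.000  0.013 -0.153  0.095
#> F4  0.040  0.119  0.013  1.000 -0.001  0.088
#> F5  0.246 -0.075 -0.153 -0.001  1.000 -0.072
#> F6  0.112  0.074  0.095  0.088 -0.072  1.000

round(b[["p_benjamini_hochberg"]], 3)
#>       F1    F2    F3    F4    F5    F6
#> F1   NaN 0.989 0.989 0.975 0.337 0.755
#> F2 0.989   NaN 0.755 0.755 0.755 0.755
#> F3 0.989 0.755   NaN 0.989 0.755 0.755
#> F4 0.975 0.755 0.989   NaN 0.989 0.755
#> F5 0.337 0.755 0.755 0.989   NaN 0.755
#> F6 0.755 0.755 0.755 0.755 0.755   NaN
```

The features are independent uniforms, so correlations are small and the
BH-adjusted p-values sit near 1; each pair used only its own jointly
observed samples (~102 of 120 here).  The statistic diagonal is the
self-test (r = 1), while adjusted-p diagonals are `NaN`: self-tests are
not counted as performed hypotheses.  Mixed-kind tests take two matrices
sharing the sample dimension, e.g.
`runPairwise("mwu", dichotomousMatrix, continuousMatrix)`, and return
grouping features in rows and continuous features in columns.

## Command line

A thin script over the same functions ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pairstat.R", package = "pairstat"))')
Rscript $CLI simulate --features=200 --samples=500 --miss-rate=0.1 --seed=1 --out=sim
Rscript $CLI pearson --x=sim_data.csv --threads=4 --adjust=bh,by --out=res
```

This writes one CSV per requested result matrix plus a JSON metadata
sidecar.  `--help` after any subcommand lists all flags (`--na-value`,
`--feature-axis`, `--variant student|welch`, `--mode auto|exact|asymptotic`,
…).

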
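---
title: "Methods: all-pairs association testing with pairwise missing-value removal"
author: "pairstat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: all-pairs association testing with pairwise missing-value removal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairstat)
```

## The problem

Population-cohort datasets mix continuous measurements, dichotomous traits
and categorical variables across thousands of features, and rarely observe
every variable on every participant.  When all pairwise associations between
features are of interest — for instance to build association networks on the
fly — complete-case analysis discards far too much data, and imputation
injects model assumptions that downstream tests are sensitive to.  The
middle road implemented here is *pairwise deletion*: for each feature pair
$(g, h)$ with $g, h \in \mathbb{R}^S$, only the jointly observed sample
pairs

$$\mathcal{I}(g, h) = \{(g_i, h_i) \mid g_i \neq m \wedge h_i \neq m\}$$

enter the test, where $m$ is the missing-value sentinel.  The set
$\mathcal{I}$ differs for every pair and may be empty; every statistic in
this package is therefore defined (or deliberately undefined, see the
degenerate contracts below) as a function of $\mathcal{I}$ alone, and the
deletion happens inside the per-pair computation, never as a global
preprocessing step.

## Tests, p-values and effect sizes

All p-values are two-sided.  Writing $n = |\mathcal{I}|$:

* **Pearson** — sample correlation $r$; under the null
  $(r + 1)/2 \sim \mathrm{Beta}(n/2 - 1,\, n/2 - 1)$, so
  $p = 2\,F_\beta\!\left((1 - |r|)/2\right)$.  Effect size $r^2$.
* **Spearman** — $\rho$ is the Pearson correlation of tie-averaged ranks
  (the $6\sum d^2$ shortcut is invalid under ties);
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ against $t_{n-2}$.
* **Chi-squared** — $\chi^2 = \sum (O - E)^2 / E$ over the contingency
  table of the pair, $p$ from the $\chi^2_{(R-1)(C-1)}$ survival function;
  no continuity correction for $2\times2$ tables (the statistic's
  definition is taken directly from the survival-function formulation; an
  optional correction was considered and rejected to keep one documented
  behaviour).  Effect sizes $\phi = \sqrt{\chi^2/n}$ and Cramér's
  $V = \sqrt{\chi^2 / (n(\min(R, C) - 1))}$.
* **t-test** — Student (pooled variance, $df = n_1 + n_2 - 2$) or Welch
  (unpooled, Welch–Satterthwaite $df$).  Cohen's $D$ uses the pooled SD
  for Student and $\sqrt{(s_1^2 + s_2^2)/2}$ for Welch — the latter is the
  only definition consistent with declaring $D$ undefined exactly when
  $s_1^2 + s_2^2 = 0$.
* **Mann–Whitney U** — $U_1 = R_1 - n_1(n_1+1)/2$ from tie-averaged joint
  ranks.  Asymptotic mode: normal approximation with tie-corrected
  variance $\sigma^2 = \frac{n_1 n_2}{12}\left((n+1) -
  \frac{\sum(t^3 - t)}{n(n-1)}\right)$ and a $0.5$ continuity correction
  toward the mean (the correction is on by default, mirroring the common
  reference implementations, and can be disabled).  Exact mode: the null
  distribution of $U$ is built by the counting recurrence
  $f(n_1, n_2, u) = f(n_1 - 1, n_2, u - n_2) + f(n_1, n_2 - 1, u)$ and the
  two-sided p doubles the smaller tail, clipped at 1.  The `auto` mode
  uses the exact computation iff the pair is tie-free and
  $\min(n_1, n_2) < 8$.  The effect size is reported as
  $r = |z|/\sqrt{n}$ from the asymptotic $z$ (sign dropped; the field's
  naming of this quantity as "Pearson r" does not fix a sign convention).
* **ANOVA** — $F = \frac{SS_b/(k-1)}{SS_w/(n-k)}$, $p$ from
  $F_{k-1,\,n-k}$; partial $\eta^2 = SS_b/(SS_b + SS_w)$.
* **Kruskal–Wallis** — tie-corrected
  $H = \left[\frac{12}{n(n+1)}\sum R_k^2/n_k - 3(n+1)\right] / C$ with
  $C = 1 - \sum(t^3 - t)/(n^3 - n)$, $p$ from $\chi^2_{k-1}$;
  $\eta^2 = (H - k + 1)/(n - k)$.

### Degenerate contracts

Degenerate pairs return `NaN` fields, never errors, so that all-pairs runs
always complete:

| situation | behaviour |
|---|---|
| correlations, $n \le 1$ | coefficient and p undefined |
| correlations, $n = 2$ | coefficient $\pm 1$, p undefined |
| zero variance in either vector | coefficient and p undefined |
| chi-squared, a full-feature category emptied by deletion | all outputs undefined |
| chi-squared, single-category feature | p and $V$ undefined ($\chi^2 = 0$, $\phi = 0$) |
| t-test, a group with $< 2$ samples or $n < 3$ | all undefined |
| Student with zero pooled SD | all undefined |
| Welch with $s_1^2 + s_2^2 = 0$ | $D$ undefined; $t = \pm\infty$, $p = 0$ if the means differ, else undefined |
| MWU, an empty group | all undefined |
| ANOVA, an empty group | all undefined |
| ANOVA, all within-variances zero | $F = \infty$, $p = 0$ if group means differ (within $10^{-12}$), else undefined |
| Kruskal–Wallis, $n \le k$ | $\eta^2$ undefined |
| all pooled values tied | rank statistics undefined |

Two wording choices were genuinely open and are resolved as follows.  The
Pearson low-$n$ thresholds are taken as $n \ge 2$ for $r$ and $n \ge 3$
for $p$ (the degrees of freedom $n - 2$ must be positive), consistent with
the Spearman convention.  The ANOVA zero-variance tiebreak compares group
*means* (within an absolute tolerance of $10^{-12}$) rather than group
sums: the F statistic is a function of means, and raw sums conflate group
sizes.

## Engine design

The engine enumerates unordered pairs once for homogeneous tests and
mirrors the result (guaranteeing exact symmetry); the diagonal of the
statistic and unadjusted-p matrices holds self-tests (e.g. $r = 1$),
while adjusted-p diagonals are forced to `NaN` because a feature tested
against itself is not a performed hypothesis.

The unit of parallel work is one *feature*, not one pair: for rank-based
tests each worker sorts its continuous feature once and re-ranks every
jointly observed subset in a single linear scan over the presorted order
(`presortFeatures()` / the internal subset re-ranker), which avoids a sort
per pair.  For Pearson, a worker sweeps its feature against all others
with masked cross-products (features are pre-centered by their observed
means, which correlation is invariant to, to keep the one-pass sums
well-conditioned).  Workers are forked processes (`parallel::mclapply`);
since no worker mutates shared state and assembly is by index, results
are bit-identical for every thread count — the determinism contract that
the test suite asserts at 1, 2 and 8 threads.

Multiple-testing correction (Bonferroni, Benjamini–Hochberg,
Benjamini–Yekutieli) delegates the step-up arithmetic to
`stats::p.adjust`, applied to the upper triangle only for homogeneous
matrices (each unordered pair is one hypothesis) and to all cells for
mixed matrices; undefined p-values are excluded from the effective test
count $m$.

## The simulator and what it does (not) capture

`simulateMatrix()` reproduces the benchmark-style conditions used
throughout the tests: continuous features i.i.d. uniform on $[0, 1]$;
categorical features label-encoded $0..c-1$ with $c = 4$ by default and
every label guaranteed present per feature (one shuffled copy of each
label plus uniform draws).  `injectMissing()` adds per-feature
missingness:

* **MCAR** — exactly $\mathrm{round}(\text{rate} \cdot S)$ entries per
  feature at uniform positions;
* **MAR** — per-entry Bernoulli with probability
  $\mathrm{logit}^{-1}(\alpha z + b)$ where $z$ is the standardized value
  of a *driver* feature (the next feature, wrap-around), taken from the
  complete pre-injection matrix so the mechanism depends only on
  ("would-be observed") driver values;
* **MNAR** — the same logistic form in the entry's own value.

The slope defaults to $\alpha = 3$ (a clearly non-ignorable but not
degenerate mechanism: the missingness odds span roughly $e^{\pm 3}$ across
the data range) and the intercept $b$ is solved numerically so the
expected missing fraction equals the target rate.  Simulation is serial
and driven by a single seed, so identical seeds reproduce matrices
bit-exactly regardless of how many threads later analyse them.

The generator deliberately does *not* emulate correlated feature
structure, realistic cohort marginals, or any particular external
implementation of MAR/MNAR defaults.  Passing tests therefore demonstrate
the correctness of the statistics and of the deletion/threading machinery
under controlled conditions — not that any real cohort satisfies the
mechanisms' assumptions.

## Numerical choices and problem sizes

Correlation coefficients are clipped to $[-1, 1]$ before p-value
evaluation; variances that are non-positive after rounding are treated as
zero (degenerate).  Exact Mann–Whitney counts are built in double
precision, exact up to the default feasibility bound
`maxProduct = 10000` (counts stay below $2^{53}$ there); beyond it the
function refuses and points to the asymptotic mode.  The logistic
intercept is solved by `uniroot` on $[-50, 50]$ to tolerance $10^{-10}$.

The shipped test suite validates every statistic and p-value cell-by-cell
against base R's reference implementations (`cor.test`, `chisq.test`,
`t.test`, `wilcox.test`, `oneway.test`, `kruskal.test`) applied after
manual pairwise deletion, on $15 \times 40$ matrices at 0%, 10% and 50%
missingness; the exact U distribution against full enumeration for all
group sizes with $n_1 + n_2 \le 10$; the adjustment routines against
hand-written step-up formulas on vectors up to length 10,000; thread
invariance on a $200 \times 500$ matrix; and an all-pairs Pearson sweep of
a $1{,}000 \times 1{,}000$ matrix with 10% missingness, the scale the
package is designed to handle interactively on a single workstation.

## A worked example

```{r example}
x <- simulateMatrix(6, 120, kind = "continuous", seed = 11)
x <- injectMissing(x, 0.15, "MCAR", seed = 12)
b <- runPairwise("pearson", x,
                 outputs = c("statistic", "p_unadjusted",
                             "p_benjamini_hochberg"))
round(b[["statistic"]], 3)
round(b[["p_benjamini_hochberg"]], 3)
```

Independent uniform features: small correlations, BH-adjusted p-values
near 1, and `NaN` diagonals on the adjusted matrix (self-tests excluded).

## Known limitations

Only the seven listed tests are available; covariate adjustment, paired
designs, one-sided alternatives and post-hoc procedures are out of scope.
The engine targets a single shared-memory machine; the pair grid is held
densely in memory, so millions of features would require a distributed or
out-of-core design.  MAR here conditions on a single driver feature, a
simple documented mechanism rather than a general missingness model.
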
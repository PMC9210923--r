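---
title: "Selecting discovery thresholds with FDR confidence intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting discovery thresholds with FDR confidence intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdrscan)
library(dplyr)
```

## The problem

In large-scale testing — omics association scans being the canonical case —
the false discovery rate is increasingly treated as a parameter to *estimate*
rather than a level to fix in advance: an investigator proposes a series of
candidate p-value cutoffs, estimates the FDR at each, and chooses a rejection
region in light of the estimates, the number of discoveries, and the cost of
follow-up. Two things are needed to make that workflow honest. First, an FDR
estimate is only as useful as its precision, so each estimate needs a
confidence interval. Second, *choosing* a threshold because its interval
looks favorable is a selection event: intervals picked that way no longer
carry their nominal coverage, in exactly the way that reporting confidence
intervals only for "significant" effects biases them.

`fdrscan` implements both halves: a permutation-based pFDR estimator with
delta-method intervals on the log scale, and a false coverage-statement rate
(FCR) procedure that selects thresholds whose intervals exclude 1 via
Benjamini–Hochberg step-up on per-threshold Wald tests, then widens the
selected intervals so that post-selection coverage is retained.

## The estimator

For `m` exchangeable tests and a cutoff `t`, let `S` be the observed number
of p-values below `t` (strict comparison), and let `V_1, ..., V_P` be the
rejection counts from `P` analyses in which the outcomes were permuted
jointly against the predictors. Writing `Vbar` for their mean,

$$\hat\pi_0 = \frac{(m - S)/m}{(m - \bar V)/m} \;\wedge\; 1, \qquad
\widehat{FDR}_t = \hat\pi_0\,\frac{\bar V_t}{S_t} \;\wedge\; 1 .$$

`Vbar` estimates the expected number of *null* rejections at `t` scaled to
all `m` tests being null; multiplying by the null-proportion estimate and
dividing by the observed count gives the familiar plug-in pFDR,
targeting $E[F/S \mid S>0]$. The estimate is undefined when `S = 0` (the
conditioning event failed) and such rows are excluded from selection and
from coverage accounting throughout.

The variance of the log estimate combines the two sampling sources:

$$\sigma^2_{\log} = \frac{m - S}{m\,S}
  \;+\; c_1\,\frac{m - \bar V}{P\,m\,\bar V}.$$

The first term is the binomial-style uncertainty in the observed count; the
second is the Monte-Carlo uncertainty in `Vbar`, which decays as `1/P` — the
interval honestly reflects how many permutations were run. The factor
$c_1$ absorbs over-dispersion of the permutation counts relative to
binomial, which is how dependence among tests (correlated features give
correlated rejections) enters the interval. By default $c_1$ is estimated
per threshold as the ratio of the sample variance of the `P` counts to the
binomial variance $m\,(\bar V/m)(1-\bar V/m)$, floored at 1: counts are
never treated as *under*-dispersed, and with small `P` a fixed `c1` can be
supplied instead. Intervals are log-normal,
$\exp\{\log\widehat{FDR}_t \pm z_{(1-cl)/2}\,\sigma_{\log}\}$, so they are
positive, multiplicative-symmetric, and their upper bound may exceed 1 —
deliberately, because the selection rules below compare the upper bound
against 1.

Everything above depends on the data only through `m`, `S`, and the
permutation counts: `fdr_table_counts()` accepts pre-reduced counts and is
bit-identical to `fdr_table()` on raw p-values, which is what makes the
method practical at biobank scale (filter results above the loosest
threshold, keep counts).

### Numerical choices

* **Boundary rule.** `p < t` strictly, applied identically to observed and
  permuted p-values; configurable via `rule = "nonstrict"`.
* **Cap at 1.** pFDR cannot exceed 1, so the point estimate is truncated for
  reporting and Wald testing; a capped row has $Z_t = 0$, $P_t = 0.5$, and
  can never be selected at any reasonable level.
* **Zero permutation counts.** If `S > 0` but no permutation rejected
  anything, `Vbar` is replaced by `0.5/P` (half a count spread over the
  permutations) and the row flagged `vbar_adjusted`; this avoids `log(0)`
  while staying conservative, and the row remains eligible for selection.
* **Degenerate `S = m` or `Vbar = m`.** The corresponding variance term is
  clamped at 0 rather than going negative.

## Selection and FCR adjustment

Each threshold gets a one-sided Wald test of $H_0: \log FDR_t = 0$ against
$\log FDR_t < 0$, $P_t = \Phi(\log\widehat{FDR}_t / \sigma_{\log})$. The
step-up rule sorts the $|T|$ p-values and takes
$R = \max\{i : P_{(i)} < i\alpha/|T|\}$; the selected thresholds are those
with $P_t \le P_{(R)}$ (ties at the critical value included — standard BH
rejection-set semantics, and deterministic). Their intervals are then
recomputed at level $\alpha^* = R\alpha/|T|$: strictly wider than the
nominal ones whenever $R < |T|$, identical when everything is selected.
Under positive regression dependence — plausible here because nested
rejection regions make the per-threshold statistics positively related —
this structure controls the FCR at $\alpha$: among selected intervals, the
expected proportion failing to cover their true FDR stays below $\alpha$.

Two naive comparators are included because they are what practitioners
otherwise do: select thresholds whose (unadjusted) interval upper bound is
below 1 (`select_ucb()`), or whose point estimate is below 0.2
(`select_point()`). Both are evaluated on unadjusted 95% intervals; both
ignore selection and pay for it under the global null.

## What the simulation engine emulates

`scenario_spec()` reproduces a block-correlated association-scan caricature:
`n = 200` samples, 100 Gaussian predictors in 20 independent blocks of 5
with within-block (compound-symmetric) correlation $\rho = 0.3$, one
Gaussian outcome per block, and marginal slope tests for all
$100 \times 20 = 2000$ predictor–outcome pairs. Predictor blocks are drawn
exactly through the one-factor representation
$X = \sigma(\sqrt{\rho}\,u\mathbf{1}' + \sqrt{1-\rho}\,Z)$, which has
covariance $\sigma^2[(1-\rho)I + \rho J]$ by construction. The marginal
scale $\sigma$ is 1 for both predictors and outcome noise — the
standardized-scale reading, adjustable in `scenario_spec()` for
sensitivity checks. The
marginal test is the simple-linear-regression slope t-test (identical to
the correlation t-test on $n-2$ df); permutation analyses permute the
outcome *rows* jointly, preserving dependence within the predictor and
outcome sets while breaking all cross associations.

The named scenarios place all-0.05 or all-0.075 coefficient vectors in the
first 5 or 10 blocks (A–D) or nowhere (E, the global null). Within a
non-null block every predictor is marginally associated with the block's
outcome (directly or through $\rho$), so the truly null pairs are exactly
the cross-block pairs plus the pairs of null blocks — which is what makes
the false-discovery count `F` observable inside the simulation.

Things real data have that this design does not: heavy-tailed or discrete
test statistics, negatively dependent tests, heterogeneous block sizes and
correlation strengths, and composite effects spanning blocks. Passing the
coverage study therefore demonstrates calibration under moderate positive
dependence with weak dense signal, not universal robustness.

### The true-FDR oracle

Coverage needs a truth to cover. `true_fdr_curve()` estimates
$E[F/S \mid S>0]$ per threshold from an independent Monte-Carlo run of the
same scenario (default 10 000 replicates; the per-threshold MC standard
error is reported alongside). Under the global null the curve is
identically 1 by definition and no simulation is run. Replicate thresholds
with `S = 0` contribute no interval and are excluded from the replicate's
`Q` denominator — no interval exists to cover or miss; `Q` is defined as 0
when nothing is selected at all. Coverage is judged on the raw FDR scale
(equivalent to the log scale by monotonicity, and it avoids taking logs at
the global-null boundary value of 1).

## The coverage study

`run_coverage_experiment()` repeats the whole pipeline — simulate, test,
permute 20 times, estimate, select by all three rules, score each selected
interval against the oracle curve — and reports per method the mean `Q`
(the FCR estimate), `coverage = 1 - mean(Q)`, and the fraction of
replicates with at least one selected interval whose upper bound is below
1, i.e. the rate of asserting "some discoveries are real". Under the global
null that assertion is always wrong, so for the upper-bound rule the
coverage and the assertion rate are complementary by construction — a
useful internal identity that the tests assert exactly.

Every replicate runs on a seed derived from the master seed, so summaries
are bit-reproducible and independent of evaluation order; the oracle uses
its own derived seed. The packaged validation (see
`tests/testthat/test-acceptance.R`) runs the global-null scenario at 2000
replicates and the four signal scenarios at 500 replicates with a
5000-replicate oracle, sizes chosen to keep the default check suite brief
while leaving Monte-Carlo error well inside the comparison tolerances
(±0.02 coverage at 2000 replicates, ±0.03 at 500); `scripts/acceptance.R`
re-runs all reported quantities at the full 2000 replicates with a
10 000-replicate oracle.

```{r small-study, eval = FALSE}
sp <- scenario_spec("A")
ex <- run_coverage_experiment(sp, n_rep = 500, seed = 1, n_mc_oracle = 5000)
tidy(ex)
conditional_coverage(ex) |> plot_conditional_coverage()
```

Conditional coverage — coverage among selected intervals, binned by the
true FDR — is the harsher lens: a method can control FCR overall yet fail
conditionally where its selection rule and the truth disagree. The
point-estimate rule shows exactly this between true FDR 0.2 and 0.5, where
an interval is selected only when the estimate has strayed below its
target; the bin edges are configurable (`breaks`), defaulting to width-0.05
bins on [0, 0.5].

## Design choices that were genuinely open

* **Tie handling at the step-up critical value** follows the standard BH
  rejection set (include ties); with continuous Wald p-values ties have
  probability zero, so this only matters for degenerate count patterns.
* **The comparator rules use unadjusted intervals** — they model the naive
  practice the FCR procedure is meant to replace, and the global-null
  complementarity identity only holds for the unadjusted upper bound.
* **`Q` excludes replicate-thresholds with `S = 0`** rather than counting
  them as covered; sensitivity to this choice is limited to the strictest
  grid points, where selections are rare in the first place.
* **Per-threshold `c1`** rather than a pooled estimate: dispersion varies
  strongly along the grid (loose thresholds have large, strongly dependent
  counts), and the floor at 1 keeps the strict-threshold rows, where the
  variance ratio is noisy, from under-covering.

## Limitations

The Wald test and the log-normal interval are asymptotic in the rejection
counts; at thresholds with a handful of discoveries the intervals are wide
and the test is conservative, which is visible as the method selecting
mostly mid-grid thresholds. The FCR guarantee is inherited from step-up
selection under positive dependence; adversarial negative dependence is not
covered by the theory or by the simulation design. And the oracle curve is
itself a Monte-Carlo estimate: coverage comparisons inherit its (reported)
standard error, which matters only in bins with few selected intervals.
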
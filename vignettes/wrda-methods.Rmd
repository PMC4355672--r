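---
title: "Weighted relative difference accumulation for short two-group time series"
author: "wrda package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted relative difference accumulation for short two-group time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrda)
```

## The problem

Short longitudinal two-group omics designs — a handful of time points, a
few samples per group per point — are common in metabolomics: a disease
model followed against controls over weeks, or a screening cohort whose
cases are aligned backwards from diagnosis. Static per-time-point
differential testing ignores that a biologically meaningful feature may
diverge gradually, transiently, or only at specific stages. This package
ranks features by accumulating their between-group separation *along the
whole time course*, with explicit control over how much each stage
contributes.

## The score

Samples carry a group label (control `C` vs model `M`), a time-point
index $i = 0, \dots, N-1$, and a sampling-time index $j$ within each
time point. Index 0 is the reference stage: the diagnosis stage in a
prospective design, the batch with the shortest storage time within a
stage. For feature $f$ let $\mu_{g,f}(i,j)$ and $\sigma_{g,f}(i,j)$ be
the group mean and sample standard deviation in stratum $(g, i, j)$.

With time-point weights $\omega_i \ge 0$ and sampling-time weights
$k_j \ge 0$, the package computes

$$D(f) = \sum_i \omega_i \sum_j k_j \, \bigl|\mu_{C,f}(i,j) - \mu_{M,f}(i,j)\bigr|,
\qquad
S(f) = \sum_i \omega_i \sum_j k_j \, \bigl(\sigma_{C,f}(i,j) + \sigma_{M,f}(i,j)\bigr),$$

$$\mathrm{score}(f) = \frac{D(f)}{S(f) + \epsilon}.$$

$D$ accumulates the weighted between-group mean separation; $S$
accumulates the within-group scatter on the same weights, so the score
is a SAM-style relative difference integrated over the design.
$\epsilon$ (default 0.005) regularizes features whose accumulated SDs
are near zero. With a single sampling time per point and $k = (1)$ the
double sum collapses to the plain time-point form (`wrdaScore`); the
two functions share one code path, so the reduction is exact to the
bit, which the test suite asserts.

Two choices in this aggregation are not forced by the score's verbal
definition and are isolated in one internal function so alternatives
are one-line swaps: $S$ is $\omega$- and $k$-weighted exactly like $D$
(an unweighted $S$ would break the scale covariance noted below), and
$k$ sits outside the absolute value (weights attenuate evidence, they
do not flip signs).

Numerical conventions:

* $\sigma$ uses denominator $n-1$; singleton strata get $\sigma = 0$
  with a diagnostic rather than an error, so sparse cohort cells never
  crash scoring.
* $\epsilon = 0$ is permitted; $D = 0$ maps to score 0, so $0/0$ never
  occurs. With $\epsilon = 0$, scaling all weights by $c > 0$ cancels
  between $D$ and $S$ and leaves every score unchanged; with normalized
  weights this holds for every $\epsilon$.
* Ties in ranking break by feature input order, stable across runs.
* A stratum missing one group is an error only if it carries positive
  weight; zero-weight strata are fully inert.

## Weight families

`makeWeights(family, q, n)` generates $\omega$ (length $N$) or $k$
(length $p_i$, regenerated per time point when $p_i$ varies) from

| family | formula | behavior |
|---|---|---|
| equal | $1$ | all stages matter equally |
| linear | $1 + (n-i-1)q$ | arithmetic decline |
| proportional | $(1+q)^{\,n-i-1}$ | geometric decline |
| exponential | $e^{(n-i-1)q}$ | steepest decline |

The changing factor $q \ge 0$ sets the steepness; every family
collapses to equal weights at $q = 0$, exactly. Index 0 always receives
the maximum. Weights are normalized to sum 1 by default: the published
examples of hand-set weights (1/8 each; 0.3/0.3/0.4) are on that scale,
and normalization gives $\epsilon$ a scale-stable meaning. Ranking
within a fixed scheme is unaffected by normalization; only
cross-scheme FDR comparisons could shift through $\epsilon$, which is
why the grid search normalizes consistently. `explicitWeights()` wraps
prior-knowledge vectors verbatim, zeros allowed.

## Preprocessing

Two rules, both stratified by (group, time point):

* **Zero filter** — a feature is dropped when more than 20% (strictly)
  of its values in any stratum are zero. Evaluating per group rather
  than pooled is deliberate: a feature undetectable in either group at
  any stage cannot be summarized there.
* **Outlier correction** — values outside $\mu \pm 2\sigma$ (statistics
  computed over the whole stratum, outliers included) are replaced by a
  normal draw fitted to the stratum's non-outlier values, rejected
  until inside the range. The replacement distribution is a modelling
  choice — normal is the minimal assumption consistent with the score's
  own mean/SD machinery — and the draw is seeded, so the pipeline is
  bit-reproducible. $\sigma = 0$ strata cannot contain outliers (the
  range collapses onto the only value present) and are no-ops.

## Permutation null, FDR, and noise filtering

Group labels are shuffled **within each (time point, sampling time)
stratum**, the only scheme that preserves the time design and the
per-stratum group sizes. $B = 200$ permutations is the conventional
default. For small designs `exhaustive = TRUE` enumerates every
distinct stratified assignment, making downstream estimates exact.

The FDR at a top-$n$ cut is the SAM-style estimate
$\min\!\bigl(1, \frac{1}{Bn}\sum_b \#\{f: s^0_{b,f} \ge s_{(n)}\}\bigr)$
with $s_{(n)}$ the $n$-th largest observed score — mean exceedance
count, no $\pi_0$ correction (a median variant is available). The
*lowest FDR* over the cut grid $n \in \{50, 45, 40, 35, 30\}$ is the
scheme-selection criterion, ties resolved toward the largest $n$.

The level-1 **noise filter** retains a feature only if its observed
score exceeds the 0.95 quantile of the pooled null scores. By
construction this retains about 5% of truly null features (the test
suite checks the binomial calibration), while features with real
accumulated divergence sit far above the pooled null. The quantile is
configurable, and the post-filter FDR curve is always reported so a
stricter criterion (e.g. FDR 0 at the reporting cut) can be applied.

## Weight-function grid search

`gridSearch` evaluates every (k family, $q_k$) × ($\omega$ family,
$q_\omega$) cell — equal plus three parametric families with
$q \in \{0.1, \dots, 1.0\}$ in steps of 0.1, i.e. 31 settings per axis
by default — by its lowest FDR. One permutation stream, derived from
the single seed, is shared by all cells: every cell is measured against
the identical relabelings, so cross-cell FDR differences are paired
comparisons rather than independent Monte Carlo draws, and the
per-permutation group summaries (which do not depend on the weights)
are computed once and reused, which is what makes the ~1000-cell grid
tractable. Scores for all cells come from one matrix product per
permutation.

`selectWeights` applies the documented tie-break: among minimal-FDR
cells, first the family pair contributing the most tied cells, then the
smallest $q_k$ (minimizing weight disparity among sampling times), then
the smallest $q_\omega$. The k layer is resolved before $\omega$.
`familyPreference` tallies which family pairs most often fall under an
FDR ceiling — evidence about functional form that is more robust than
the single selected cell.

## Two-level workflow and validation

`runTwoLevel` chains the pieces for single-batch designs: equal-weight
scoring plus permutation noise filtering (level 1, yielding feature
subset 1), then rescoring of the survivors with explicit stage-focused
weights (level 2). Downstream, `svmValidate` runs stratified 5-fold
cross-validation of an SVM repeated 50 times. The SVM kernel is RBF
with library defaults (linear by flag) — the kernel is a reporting
convention here, not part of the method — and standardization uses
training-fold statistics only, avoiding leakage. Accuracy SD is across
repeats. `rocAuc` is the midrank Mann–Whitney AUC; an independent
brute-force pairwise count and the pROC package both serve as oracles
in the tests. `reportTables` adds Welch (default) or Mann–Whitney
p-values at the reference stage alone and pooled over all samples; the
test is labelled in the output because the choice is conventional, not
prescribed.

## The synthetic generator

`simulateTimeCourse` draws control values as
$\mathcal{N}(b_f, s_f)$ with per-feature baselines $b_f$ spread
uniformly within ±50% of `baselineMean` and $s_f$ proportional to
$b_f$; planted signal features shift the M group by
$\delta \, s_f \times \text{profile}(i) \times \text{storageDecay}^j$.
Profiles: `step` (abrupt onset), `ramp` (gradual), `expdecay`
(strongest at the reference stage, fading backwards — the prospective
geometry). Zero inflation is applied before outlier spikes, mirroring
acquisition dropouts versus measurement artifacts; intensities truncate
at zero.

Two presets fix the study conditions used throughout the tests:

* **ratDefaultSpec** — $N = 8$, one sampling time, 10 samples per group
  per point, 1000 features, 30 planted at $\delta = 1.5$ SD with step
  onset at the 5th point. Under these conditions equal-weight scoring
  recovers on average ≥ 90% of the planted features in the top 30
  (measured across 5 seeds).
* **cohortDefaultSpec** — $N = 5$ stages × 4 sampling times, 3 cases vs
  6 controls per stratum (few cases against matched double controls),
  exponential-decay divergence (rate 0.5) with storage attenuation 0.8
  and 2% zero inflation.

The generator is deliberately idealized: Gaussian, uncorrelated
features, additive effects. It exercises exactly the moments the score
uses, so passing tests demonstrate correctness of the machinery and
recoverability under the stated geometry — not performance on real
LC-MS intensities, which are skewed, heteroscedastic and correlated
(a log-normal baseline and correlated blocks are the obvious
extensions).

## Problem sizes in the shipped checks

The test suite and the acceptance script keep full-scale defaults where
they are cheap (1000 features, $B = 200$, the full 961-cell grid at 500
features) and scale down only the purely combinatorial checks (oracle
comparisons on ≤ 20 features, exhaustive enumeration on 8 samples).
Null-calibration checks use 500 features over 4 time points with 5
samples per group per point. These sizes are stated here so results are
interpreted at the scale they were computed.

## Known limitations

* Two groups only; no multi-class extension.
* $\epsilon$ is global, not per-feature adaptive (no SAM-style $s_0$
  percentile tuning).
* The FDR estimator uses the raw mean exceedance count; with strong
  signal it is conservative (no $\pi_0$), with tiny nulls it is noisy.
* The noise-filter quantile rule is one defensible formalization of
  "remove features indistinguishable from label noise"; alternatives
  (per-feature permutation p-values with multiplicity control) are out
  of scope.
* Continuous optimization of $q$ is not attempted; the grid mirrors the
  intended use where $q$ differences below 0.1 are immaterial.
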
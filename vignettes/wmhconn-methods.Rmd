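---
title: "Models and methods behind wmhconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wmhconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhconn)
```

This vignette is the package's account of its statistical models: what
each stage assumes, which tunables matter, how the synthetic-data
generator is built and what passing tests on it do and do not show, and
where genuinely open design choices were settled.

## The scientific setting

White-matter hyperintensities (WMH) are FLAIR-bright lesions of cerebral
white matter whose volume rises steeply — roughly exponentially — with
age and which accompany declines in speed-dependent ("fluid") cognition.
The package implements the statistical chain used to relate three layers
of measurement in an adult-lifespan cohort: a phenotype table (age, a
12-test cognitive battery, log WMH volumes at two lesion-classification
thresholds k ∈ {0.5, 0.7}, tract-level WMH), and one weighted, undirected
246-node structural connectome per participant (streamline counts from
tractography, entries below 3 streamlines zeroed).

## Cognitive factor scores

Test scores are first residualized on vocabulary and sex by OLS — the
package's reading of "controlling for" a covariate, chosen because it is
explicit, linear, and makes the residuals exactly orthogonal to the
covariates. The general fluid-cognition score is the first unrotated
factor of an iterated principal-axis analysis (squared multiple
correlations as starting communalities; leading eigenvector of the
reduced correlation matrix; iteration to a communality tolerance of
1e-6, at most 100 steps, non-convergence is an error, Heywood cases are
clipped with a warning). Factor scores use the regression (Thurstone)
estimator by default; Bartlett weighting is available and is also the
robust choice for exactly singular batteries. The sign convention —
first test's loading non-negative on a higher-is-better battery — makes
the fluid score decline with age, matching the field's reporting
convention.

## Correlation and power machinery

WMH volumes enter all analyses as natural logs (the base only rescales,
never reorders, correlations). Partial correlations are Pearson
correlations of OLS residuals with `n - 2 - c` degrees of freedom (the
Fisher convention; stated here because conventions differ). FDR control
is Benjamini–Hochberg within explicitly declared families — one family
per analysis table, never pooled across tables. Power for a Pearson r
uses the Fisher-z approximation, which reproduces the standard design
calculation `power_pearson(0.35, 68, 0.05)` ≈ 0.84.

A note on arithmetic: with zero-order correlations (0.68, −0.68, −0.859)
among log WMH, fluid cognition, and age, the partial correlation of WMH
and cognition given age is (−0.68 − 0.68·(−0.859)) / √((1−0.68²)(1−0.859²))
≈ −0.256 by the closed form. Published analyses working from unrounded
data report values near −0.27 for this quantity; the gap is explained
entirely by input rounding, so the package's tests pin the closed form,
not any printed value.

## PLSR, cross-validation, and importance

The whole-brain model is SIMPLS on column-centered data: components are
extracted from the SVD of the X–Y cross-product with loading-space
deflation, giving nested coefficient matrices. Outcomes are kept on
their raw scales by default, so the baseline MSE equals the sum of the
outcome sample variances — with age in years this sits near 300 for an
adult-lifespan cohort, which is the bookkeeping convention under which
CV-MSEP and CV-PCTVAR = 100·(1 − CV-MSEP/baseline) are reported.
Fivefold component selection uses a seeded unstratified random
partition; the chosen component count minimizes CV-MSEP with ties going
to the smaller count.

Two conventions deliberately coexist: the raw-outcome fit defines
CV-MSEP/CV-PCTVAR, while feature importance (cross-fold mean |β|,
averaged across outcomes; ROI importance as the incident-edge sum) is
computed from standardized-outcome fits. With raw outcomes the age
column's variance dominates the covariance criterion and the coefficient
magnitudes, so edge ranks would mostly reflect the age scale rather than
cross-outcome signal; standardizing the outcomes makes the |β| values
comparable across outcomes before averaging.

Two algorithmic facts the test suite leans on: SIMPLS equals OLS when
the component count reaches the predictor rank, and SIMPLS coincides
with NIPALS for a univariate outcome (for multivariate outcomes the two
algorithms differ beyond the first component, so the NIPALS cross-check
is run on a univariate toy). Exact noiseless recovery in cross-validation
is only guaranteed when the Krylov dimension of the problem is within the
component budget, which the test constructs via a rank-3 predictor block.

## Resampling against a permuted-outcome null

Subnetwork models restrict the edge set by mask: SUB–SUB (630 edges for
a 36-node subcortex) and SUB-to-network masks (36 × 30 edges each for
seven 30-node cortical networks). Each of `n_iter` iterations draws an
80/20 split, selects the component count by inner fivefold CV *on the
training set of that iteration*, fits, and scores the mean over outcomes
of the held-out observed–predicted Pearson r. The null twin runs the
identical procedure with the outcome rows jointly permuted afresh each
iteration — permuting rows as a block preserves the outcomes'
inter-correlations under the null, which is the package's interpretation
of permuting "the set of target variables". Effect sizes are the
two-sample KS statistic (asymptotic p) and Cohen's d with pooled SD;
distribution summaries are the median and the 2.5/97.5 empirical
percentiles under the linear-interpolation quantile rule (type 7; at
5000 iterations the rule choice moves the interval only in the third
decimal). The full design uses 5000 iterations; the tests run 120–500,
which is enough for Cohen's d to stabilize well past the decision
thresholds.

## Graph metrics

The metric formulations are the field-standard readings of their verbal
definitions, each swappable behind its own function:

- **Density**: fraction of node pairs with nonzero weight.
- **Clustering**: Onnela's weighted coefficient on weights normalized by
  the matrix maximum, mean over nodes; degree < 2 contributes 0.
- **Modularity**: Newman's weighted Q with resolution γ. The a-priori
  partition is the atlas's eight networks (seven cortical + subcortical).
  Weighted edges are used throughout (whether to binarize is not
  recoverable from verbal definitions; weighted is the choice here).
- **Consensus modularity**: Louvain (igraph, resolution γ) repeated
  `n_runs` times; co-assignment matrix thresholded at τ = 0.5;
  re-clustered until all runs agree (at most 20 rounds), in the
  Lancichinetti–Fortunato style. Defaults: 100 runs at full scale,
  reduced in the demo pipeline.
- **Communicability**: mean off-diagonal of exp(S^(−1/2) W S^(−1/2))
  with S the diagonal strength matrix (Crofts–Higham normalization),
  isolated nodes excluded. This normalization makes the measure invariant
  to a global rescaling of weights, so only the weight *distribution*
  carries signal.

The association table reports, per metric, an unadjusted OLS on log
global WMH and an adjusted model adding age and fluid cognition, with
unstandardized b, standardized β, 95% CIs, and R²; a companion
Pearson/FDR table uses the correlation machinery above.

## Mediation

Paths are estimated by OLS (each mediator on [1, x]; the outcome on
[1, x, M]), indirect effects as a·b products, uncertainty by
case-resampling bootstrap with percentile intervals (the framework
default in the applied literature; BCa is deliberately not used).
Coefficients stay unstandardized with the predictor in native units
(years of age), matching how direct effects per year are reported in
this literature. Significance is keyed to the CI excluding zero; the z
statistic (point/bootstrap-SE) and its two-sided normal p are reported
alongside, as some published tables print inconsistent z/p pairs and the
CI is the decision rule.

## The synthetic-data generator

Because the motivating datasets are available only on request, the
package ships a generator whose *defaults are the study conditions*: three
age cohorts (n = 28/20/20; means 28.04/48.75/69.15; SDs 5.27/5.80/4.61;
truncation ranges 18–39/40–59/60–78), target correlations
r(age, g) = −0.859, r(age, log WMH) = 0.68, r(g, log WMH) = −0.68, log
global WMH scale 6.11 ± 1.40 (k = 0.7), auxiliary WMH series correlated
0.99 (k = 0.5 and periventricular) and 0.64 (deep) with the global
latent, domain-factor triad (0.846, 0.604, 0.557), tract-WMH loading
δ = 0.8, and a connectome density target of 0.33.

The latent model is linear-Gaussian: with standardized age z,
g = ρ_ag·z + √(1−ρ_ag²)·ε, and the WMH latent w = αz + β(−g) + γe where
(α, β) solve the 2×2 system hitting both WMH targets exactly in the
infinite-sample limit and γ normalizes var(w) = 1. Infeasible target
triples (non-positive-definite implied covariance) are rejected at
construction, never clipped. Domain factors load on g via the triad
identities (a_EF·a_PS = 0.846, etc.).

Observed test scores load 0.9 on their domain factor. This loading is a
calibration choice: the triad values above describe correlations between
*measured* factor scores, and a lower test reliability attenuates the
measured correlations below the stated band (at loading 0.8 the
composite reliability 0.877 pulls the EF–PS score correlation to ~0.74)
while full compensation through the latent triad is algebraically
impossible (it would require a loading above 1). At 0.9 the measured
triad lands within ±0.1 of its targets and the recovered general factor
correlates above 0.9 with the latent g.

Connectomes are Poisson draws around a group baseline of expected
streamline counts with block-structured support: cortical within-lobe
and within-network edges enriched (anatomical communities), subcortical–
cortical edges mildly enriched (hub-like basal ganglia and thalamus),
subcortical–subcortical support sparser, and the overall support scale
solved numerically so mean post-threshold density ≈ 0.33. The planted
signal multiplies expected counts on signal edges by exp(−κ·b) with
κ = 0.6 and b the participant's standardized WMH latent; the signal set
is all SUB–SUB edges plus half of the SUB–DMN and SUB–FPN edges,
restricted to edges with baseline support (nothing can be planted on an
edge with no streamlines). This geometry puts the aging-related loss
mostly on between-module subcortical–cortical edges of below-average-
strength subcortical nodes — the regime in which density and
communicability fall with age while modularity rises, the qualitative
pattern reported for adult-lifespan structural networks.

What the generator does **not** emulate: spatial autocorrelation of
edges, hemispheric asymmetries, realistic streamline-count marginals
(the subject-level noise model is Poisson, chosen as a simple
overdispersion-free stand-in; real count variability is not published),
non-Gaussian cognitive-score distributions, and missing data. Tests that
pass on it demonstrate that the estimators recover planted structure at
the study's scale and noise level — not that real data would show the
same effect sizes.

Tract-level WMH log-volume scales (4.2–5.5 log-mm³, SD 1.4, the anterior
thalamic radiations largest) are round-number choices at the magnitude
typical of tract lesion loads; only their shared latent (δ = 0.8)
matters to the mediation dissociation they exist to produce: the global
WMH simple model shows a clear indirect effect while no single tract
mediates independently in the parallel model.

## Numerical choices and degenerate inputs

Seeds: every stochastic routine takes an explicit seed, restores the
caller's RNG state, and the pipeline derives per-stage child seeds from
one master seed so stages are individually rerunnable. Ties in component
selection go to the smaller count. Constant columns are errors wherever a
correlation is undefined (including a mediator fully explained by the
covariates). Connectome files are validated on read with the offending
file and cell named. Quantiles are type 7 throughout. The consensus
agreement threshold τ = 0.5 follows the consensus-clustering literature;
entropy of undecided pairs is reported if agreement fails to converge.

## Problem sizes used by the tests

The shipped suite runs the full design logic at reduced Monte-Carlo
scale, chosen as the sizes at which every decision threshold is stable:
200 cohorts for calibration round-trips, 50 seeds for importance
enrichment, 500 resampling iterations (10 seeds for the null), 500
simulations at 1000 bootstrap draws for mediation coverage, and 20 seeds
for the metric sign pattern. The pipeline demo runs 50 resampling
iterations and 8 Louvain restarts per consensus call.

## Known limitations

- Only the first unrotated factor is implemented; no confirmatory or
  multi-factor models.
- The outcome-permutation null is the only null model; edge-permutation
  or degree-preserving nulls are out of scope.
- Graph metrics are global; nodal maps, rich-club and hub statistics are
  not computed.
- The generator's Poisson edge noise understates the overdispersion of
  real streamline counts; planted-signal effect sizes should be read as
  calibration checks, not forecasts.
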
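---
title: "Methods: trajectory-based analysis of aging time-course RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory-based analysis of aging time-course RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agetraj)
```

## The problem

A cohort of animals is aged under controlled conditions, deaths are recorded
daily, and groups are removed for RNA-seq at sampling points spread over the
whole lifespan. Every sample therefore carries two progression covariates:
chronological age (days) and physiological age (the fraction of the cohort
dead at sampling). The goals are (i) to find genes whose expression changes
with aging, (ii) to describe the *shape* of each gene's trajectory, not just
its direction, (iii) to quantify what a conventional 2-timepoint
young-versus-old design would have missed, and (iv) to ask whether genes
sharing a trajectory share biological functions.

`agetraj` implements this as a chain of small, separately testable stages,
plus a seeded generator that reproduces the design's statistical structure
so every stage can be validated against known truth.

## The sampling design and its mortality model

The default design samples 15 days — 3, 6, 10, 14, 17, 23, 27, 31, 36, 41,
45, 48, 52, 55, 59 — with 3 replicates at each of the first 14 points and 6
at the last, 48 samples in all. The cohort is assumed 99.9% alive at day 3
and 1.92% alive at day 59.

Survivorship between those anchors needs a parametric law. We use a Weibull,
`S(t) = exp(-(t/scale)^shape)`, with both parameters fixed in closed form by
the two anchors (shape 2.78, scale 36.0). A Gompertz hazard — the classical
aging mortality law, also provided (`gompertz_survival()`,
`calibrate_gompertz()`) — passes through the same anchors but then
concentrates nearly all deaths after day 40; on the default sampling days it
yields a day–mortality correlation of only 0.92, whereas observed fly-cohort
survivorship declines over much of the lifespan and the two covariates are
nearly collinear (r ≈ 0.98). The Weibull through the same anchors gives
r = 0.988 and is therefore the default; any survivorship function can be
passed to `make_design()` instead.

That near-collinearity is a *feature* the design emulates: the Day and
Survival analyses are expected to find almost the same genes, and the tests
assert a Jaccard overlap of at least 0.85 between their significant sets.

## The synthetic generator

`make_truth()` assigns each gene a trajectory class, a baseline normalized
mean (log-uniform on [20, 2000], spanning typical moderately-to-highly
expressed genes at ~10M reads/sample depth), a log2 effect size (default 1,
i.e. 2-fold over the lifespan — a typical strong aging effect), and an NB
dispersion (default 0.05, mid-range for bulk RNA-seq of a genetically
uniform cohort). Templates on the log2 scale:

* `null` — constant;
* `linear_up` / `linear_down` — `±effect · u`, where `u` rescales day to
  [0, 1]; strictly monotone, 2-fold total change at effect 1;
* `midlife_peak` — a raised cosine `effect · (1 − cos 2πu)/2`: equal first
  and last expected means to machine precision, maximum in midlife;
* `wave` — one full sinusoid period of peak-to-trough amplitude `effect`.
  A full period has equal endpoints for *any* phase; the phase itself is
  chosen in closed form so that the template's least-squares slope on day is
  exactly zero over the actual sampling grid. The wave class represents
  trend-free oscillation, and with unevenly spaced sampling days an
  arbitrary-phase sinusoid would carry a genuine linear component, silently
  turning "wave" genes into weak "linear" ones.

The endpoint symmetry of `midlife_peak` and `wave` is what drives the
package's central contrast result: a young-versus-old comparison is
structurally blind to these genes.

`simulate_counts()` draws per-sample size factors log-uniformly on [0.5, 2]
(typical library-depth variation, recoverable by median-of-ratios) and NB
counts with `Var = mu + alpha·mu^2`; `alpha = 0` falls back to Poisson.
Everything is seeded; identical arguments and seed give bit-identical
output.

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: batch effects correlated with age (batches are
optional, independent labels only), a mean–dispersion trend (dispersion is
i.i.d. across genes unless the user supplies a function), gene–gene
correlation beyond shared class shapes, zero inflation, and read-level
artifacts (mapping, positional bias). Results on real data additionally
depend on upstream quantification, which is out of scope.

## The differential-expression engine

All three analyses share one NB GLM engine written for this package:

* **Size factors** (`size_factors_median_of_ratios()`): per-gene geometric
  means over samples (genes positive in all samples), per-sample median of
  count/geometric-mean ratios, rescaled to geometric mean 1.
* **GLM fit** (`fit_nb_glm()`): log link, log size factors as offsets,
  dispersion fixed, IRLS with working weights `mu/(1 + alpha·mu)`.
  Convergence at max coefficient change < 1e-8, cap 100 iterations; linear
  predictors are clamped to ±30 to keep all-zero groups finite. Standard
  errors come from the Fisher information at convergence. Fits that do not
  converge are flagged and their genes reported with missing p-values,
  never significant — conservative and explicit. The fit agrees with
  `MASS::glm.nb` to ~1e-6 at matched dispersion (asserted in the tests).
* **Dispersion** (`estimate_dispersion()`): per gene, a method-of-moments
  start, then two cycles of fit-then-profile: the NB likelihood is
  maximized over dispersion with fitted means held fixed, on a log scale
  over [1e-8, 50]. Estimates are floored at 1e-8; all-zero genes are
  floored and flagged. An optional shrinkage toward an `a0 + a1/mu` trend
  exists but is off by default so simulations with known dispersion
  validate the gene-wise estimator directly. For the three analyses the
  dispersion is estimated once under the full sampling-point factor model
  and shared by every fit (including both sides of the LRT), the standard
  way to keep nested comparisons well defined.
* **Tests**: Wald `z = beta/SE` (two-sided normal) for the continuous
  covariates; LRT with chi-squared reference (14 df at 15 points) for the
  factor model versus intercept. The joint LRT — rather than per-level
  Wald tests — matches the question "does expression vary across sampling
  points at all"; this is a documented choice, since a single per-gene
  test of the factor is what the analysis needs.
* **BH adjustment** (`bh_adjust()`): the step-up definition applied
  directly, NAs excluded and reinserted, monotonicity enforced; verified
  against both `stats::p.adjust` and a brute-force evaluation of the
  definition.

Deliberate divergences from full-featured DE packages: no independent
filtering, no fold-change shrinkage, no outlier replacement. The engine is
meant to be self-contained and checkable against closed forms; its expressed
background is simply genes with row sum ≥ 1 across samples.

On pure-null simulated data the per-analysis raw false-positive rate at
nominal 0.05 stays within [0.03, 0.08] — the NB Wald test is approximate at
n = 48 — and 2-fold monotone effects at default depth and dispersion are
detected at ≥ 90% power (Day analysis, BH 0.05). Midlife-peak genes are
nearly invisible to the continuous analyses yet detected at high rate by
the LRT; the tests assert at least a 2x rate ratio.

## Z-score trajectories and clustering

For each union gene: the replicate mean of normalized expression at each
sampling point, minus the gene's overall mean across all samples, divided by
the gene's overall standard deviation across all samples. With this
construction the *replicate-count-weighted* mean of each trajectory is
exactly zero — an invariant the pipeline asserts on every run, including
the unbalanced default design (6 replicates at day 59).

Two conventions needed fixing where several readings were possible, both
recorded here as the package's choices: the overall standard deviation is
the n−1 sample SD (`stats::sd`, matching the two-point worked example
z = ∓1/√2 for values (1, 3)); and Z-scores are computed on size-factor
normalized counts — not log-transformed, not variance-stabilized — the
simplest reading, with a `log1p` option available in the pipeline
configuration for heavy-tailed data. Zero-variance genes cannot be
standardized and are excluded with a warning.

Clustering uses the Pearson dissimilarity `1 − r` between Z rows (range
[0, 2]) and agglomerative clustering via `stats::hclust`. The default
linkage is complete — the common default for this route — with average and
Ward (ward.D2) exposed, because the exploratory origin of any specific
linkage choice makes it a parameter, not a constant. The tests verify all
three linkages against a naive O(n³) Lance–Williams re-implementation.
`cut_clusters()` relabels clusters 1..k by dendrogram leaf order, making
assignments canonical and order-invariant.

The cluster count k is always the analyst's explicit choice. `scan_k()`
assists by tabulating, for candidate k, the cluster-size distribution
against a target band (50–500 genes at the reference scale of 6,142 genes,
rescaled proportionally), and recommends the smallest compliant k — but the
pipeline never adopts a recommendation silently. On the default synthetic
mixture the generative structure has five shapes; the shipped default of
k = 8 over-segments that mildly, which costs little (extra clusters simply
split shape families) while under-segmentation would merge anticorrelated
shapes. On 4-archetype mixtures with noise SD 0.3 on the z scale, cutting
at the true k recovers the construction with adjusted Rand index ≥ 0.9.

## Classifying cluster trajectories

Each cluster's representative trajectory is the unweighted mean of member
Z rows per sampling point. Classification regresses those per-point means
(15 values, unweighted) on day by ordinary least squares and applies a
Bonferroni rule: Linear if the two-sided slope p-value is below
`family_alpha / k` (0.05/28 ≈ 0.0018, printed as 0.002 at three decimals;
comparisons use full precision), signed Up or Down by the slope, else
Complex. Using the per-point means rather than all 48 replicate values is
the closest reading of a regression "between the mean Z-scores and age";
replicate-level regression would triple-count late samples in the
unbalanced design. Substituting mortality fraction or sampling-point rank
for day leaves the designations unchanged on default synthetic runs (the
covariates are nearly collinear); the acceptance tests assert this
invariance across 100 seeds.

A restricted cubic spline (natural cubic, `splines::ns`, 5 knots at evenly
spaced day quantiles with boundary knots at the day range) smooths each
mean trajectory for reporting. The smoother never feeds classification —
it exists so that plotted curves do not overfit 15 points — and with
fewer distinct days than knots it falls back to a straight line with a
warning. On the raised-cosine template the fitted curve stays within 0.1
z-units of the template at the sampled days.

Cluster names are `<Class>-<number>` with numbers running in dendrogram
leaf order within each class; naming is deterministic and bijective.

## The two-timepoint reanalysis

`two_group_de()` re-runs the engine with a single young/old indicator
(young = days {3, 6}, old = {59} by default, mirroring the common practice
of pooling the earliest samples against the last). Direction is the sign of
the fitted log2 fold change, with an exact zero broken toward "up" (an
event of probability ~0, but the tie-break is documented).
`sliding_old_window()` fixes the young set and slides the old set over
every sequential pair of later sampling days — 12 windows for the default
design, ending at {55, 59}.

`concordance()` tabulates, per trajectory class and per cluster, the
fraction of multitimepoint genes the contrast recovers, the up/down split,
and — for Linear classes only, where an expected direction exists — the
direction agreement among recovered genes. Fractions partition to 1 within
each row. The denominators are the multitimepoint union genes, so
"recovery" reads as "what the 2-timepoint design would have found of the
full result". On default synthetic mixtures, recovered Linear genes match
direction ≥ 95% of the time, Complex-class recovery sits far below
Linear-class recovery (the endpoint-symmetric templates are invisible by
construction), and the number of significant monotone genes grows as the
old window moves later in life.

## Enrichment

`enrich_all()` tests every (cluster, collection, set) triple with the
one-sided hypergeometric over-representation test — the standard statistic
for a gene list against a background — after intersecting both cluster and
set with the background (by default the expressed genes; any universe can
be supplied). BH runs within each (cluster, collection) pair, one
multiple-testing family per enrichment analysis, which mirrors running each
cluster against each collection as a separate analysis and keeps adjusted
p-values independent of unrelated analyses; the tests assert that shuffling
rows between analyses never changes any adjusted p. Collections are
ordinary GMT files; annotation content is supplied by the user, never
fetched.

## Numerical choices and degenerate inputs

* IRLS: tolerance 1e-8 on coefficients, 100 iterations, eta clamped to
  ±30; non-convergence flags the gene out of inference rather than
  erroring.
* Dispersion: floor 1e-8, profile search on log scale over [1e-8, 50],
  `optimize()` tolerance 1e-6.
* LRT statistics are clipped at 0; a full-model likelihood more than 1e-6
  below the reduced model's raises a fitting error.
* An exactly collinear design matrix raises a rank-deficiency error rather
  than silently dropping a column.
* Zero-variance genes are excluded before Z-scoring (warning, names
  recorded); constant Z rows make the Pearson correlation undefined and
  error with the offending gene named.
* `classify_cluster()` treats a numerically exact linear fit (RSS <
  1e-18) as p = 0 with the slope's sign, avoiding a 0/0 in the t
  statistic.
* Deterministic rounding of class counts in `make_truth()` uses the
  largest-remainder rule, so requested proportions are met exactly up to
  rounding.

## Problem sizes used by the tests

The suite validates the pipeline at deliberately modest scales chosen to
exercise every property while keeping a full run around a minute: null
calibration and dispersion recovery at 2,000 genes on the 48-sample design,
power and contrast mixtures at 600–1,500 genes, oracle comparisons at
n ≤ 12 (BH, hypergeometric enumeration) and n ≤ 30 (linkage), and
archetype clustering at 100 genes over 100 seeds. `scripts/acceptance.R`
re-runs the full chain at 2,000 genes. The statistical properties asserted
(error rates, power bands, recovery orderings) are scale-appropriate
analogues of the full-data behaviour, not reproductions of any specific
dataset's gene counts.

## Known limitations

* The NB Wald test is slightly anticonservative at n = 48 with estimated
  dispersion; the acceptance band [0.03, 0.08] reflects this honestly
  rather than hiding it behind moderation heuristics.
* Dispersion shrinkage is rudimentary (trend `a0 + a1/mu`, geometric-mean
  moderation) and off by default; with very few replicates per point the
  gene-wise estimator is noisy.
* Hierarchical clustering with complete linkage produces strongly uneven
  cluster sizes on mixtures dominated by two monotone shape families;
  `scan_k()` reports this but cannot fix it — choosing k remains an
  analytical decision.
* The enrichment stage assumes set membership is correct as supplied; no
  ontology-graph propagation or redundancy reduction is attempted.
* Batch structure is modelled only as an optional label; confounded
  batch–age designs are not simulated and not corrected for.
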
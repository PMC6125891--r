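---
title: "Reconstructing historical range change: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing historical range change: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The problem

Long-lived exploited mammals such as the Chinese pangolin leave a thin,
heterogeneous occurrence record: gazetteer entries, survey reports,
interview recollections, binned into decadal slices of very different
sample size (hundreds of records early, barely a hundred late). The
analysis chain reconstructs, per decade, a potential distribution from
those records plus environmental layers; asks whether the species'
realized niche contracted in environmental space; attributes the range
change to climate versus human pressure with a counterfactual projection;
and converts the latest distribution into a conservation priority ranking.

## Synthetic study system

Because the original occurrence database and GIS layers are not public,
the package generates a study system with the statistical structure the
analysis assumes:

* **Terrain and climate.** Elevation is a sum of 3–6 low-frequency
  sinusoids plus seeded Gaussian noise, scaled to roughly 100–1500 m and
  fixed across periods. MAT follows a 6.5 °C/km lapse rate plus smooth
  noise (plus an optional warming trend, default 0.2 °C per period); MAP,
  NFFD and Eref are smooth fields correlated with elevation and MAT.
  Aspect is circular uniform noise — deliberately a nuisance predictor
  carrying no signal.
* **Human pressure.** An urban-potential field concentrates near roads
  (valley-following seeded random walks) and low elevation; per-period
  urban cover is `potential^gamma_t` with `gamma` falling from 3 to 1, so
  urban growth is cell-wise monotone. Forest is the clamped complement of
  urban minus smooth noise.
* **Ground truth.** Suitability is
  `exp(−(elev−600)²/(2·300²)) · exp(−(MAT−18)²/(2·5²)) · exp(−β_t·urban)`
  with `β = (0.5, 1.5, 3, 6)` scaled by `contraction_strength` (default 1).
  Occurrences (defaults 714/561/322/117 per period, the sample sizes of
  the motivating record set) are drawn without replacement with
  probability proportional to suitability. Decline is *not* imposed on the
  counts; contraction and the upslope shift emerge from the growing urban
  term, and property tests verify both in expectation over seeds.

What the generator does **not** emulate: real spatial sampling bias within
periods (records are drawn from the true suitability, not from a
road-biased observation process), georeferencing error, temporal error in
period assignment, and land-cover vintages beyond monotone urban growth.
Passing tests therefore show that the pipeline recovers a contraction that
is really present in data of this size and noise structure — not that it
would correct biased real-world records.

## Data preparation

* **Thinning.** Greedy in input order: keep a point iff it is at least
  `d_min = max(2·√(A/π), cell)` from every kept point, where A = 6.97 ha
  is the home-range area used for deduplicating clustered records (the
  home-range circle's diameter, 297.9 m, is the natural non-overlap
  criterion; the floor of one cell, default 1 km, matches the analysis
  resolution). Kept points are deduplicated to one per raster cell.
  Greedy-in-input-order is deterministic and matches common practice; it
  is not a maximum-independent-set solver, and the thinned set is maximal
  only for that order.
* **Pseudo-absences.** 10 000 uniform draws (default) over cells within
  15 km of the road network, excluding presence cells, one seeded draw per
  period. If fewer eligible cells exist than requested, sampling falls
  back to with-replacement with a warning.
* **Collinearity.** Stepwise VIF elimination at threshold 10: while the
  maximum VIF is at or above threshold, drop the offending variable and
  recompute. Ties drop the later column in input order; an exactly
  collinear variable has infinite VIF and goes first; constant columns are
  rejected outright. On the synthetic landscape this typically removes
  elevation and MAT (both highly collinear with the other climate fields),
  leaving their proxies — analogous to the motivating analysis, where one
  period's MAT was excluded by the same rule.

## The ensemble model

Per period and repetition: stratified 80/20 presence/pseudo-absence
splits (the split fraction is the de facto standard of ensemble SDM
frameworks) for each of `runs` evaluation runs; each registered technique
is fitted with equal-total class weights (each class carries half the
total weight, so 10 000 pseudo-absences cannot swamp a hundred presences;
the weighting is configurable). Skill is TSS maximized over the threshold
grid 0.00, 0.01, …, 1.00 with ties resolved to the lowest threshold.
Members with TSS at or above the mean of all fits form the ensemble
(retaining roughly the better half); the ensemble probability is the
unweighted member mean (TSS-weighted optional); the cut-off `P` is the
TSS-maximizing threshold of the ensemble scores on the pooled data, and
presence is strictly `p > P`. Across `repetitions`, the final map is a
≥ 50 % presence vote and the consensus probability the mean. Defaults
follow the motivating design (runs = 10, repetitions = 10, ≥ 4
techniques); both the mean member TSS and a re-evaluation of the consensus
surface are logged, since either reading of a "consensus TSS" is
defensible. Permutation importance of each predictor is available as a
logged diagnostic.

The registry holds ridge logistic regression, random forest,
gradient-boosted trees, spline logistic (GAM), a shallow neural net, and a
constant-probability null baseline. These are standard, well-maintained
learners; replicating any particular legacy implementation's internals is
a non-goal — the replicated contribution is the ensemble logic
(mean-TSS selection, cut-off calibration, strict binarization, repetition
vote).

## Niche change in environmental space

The PCA-env space is calibrated on all valid cells of all periods pooled,
equally weighted, on all eight variables by default (whether human
variables belong in the PCA alongside climate is genuinely open; the
variable set is an argument). Variables are standardized; the first two
axes retained; the sign convention makes the largest-magnitude loading per
axis positive. Occurrence and availability scores are kernel-smoothed
(Gaussian, normal-reference bandwidths) on a 100 × 100 lattice spanning
the pooled availability extent; occupancy is occurrence density divided by
availability density where availability exceeds a machine-safe floor
(10⁻¹² of its maximum), renormalized. Overlap is Schoener's D; each
period's partial niche is compared with the total niche against a null of
B = 100 size-matched subsamples of the pooled occurrences, with the
add-one p-value convention (so p is never exactly zero at B = 100).

A caveat specific to availability correction: where occurrences sit in
cells of very low availability density, the ratio surface concentrates
mass on those fringe cells, deflating absolute D values. On the synthetic
landscape this effect is visible (absolute D is small), but the
*comparative* statements — the last period's partial niche less similar to
the total niche than the first's; p-values uniform when the "period" is a
true random subsample; smaller subsamples stochastically less similar —
are what the tests assert, and they are robust to it.

## Prioritization

Core-area zonation with exact (one-cell-at-a-time) removal: the marginal
loss of cell *i* is `max_j (w_j q_ij) / c_i` with `q_ij` the cell's share
of feature *j* over the cells still remaining; after each removal the
denominators are updated. No warp or edge-removal speed-ups are
implemented — at the package's grid sizes exact removal is affordable and
exactly testable (for a single feature the removal order provably equals
ascending value/cost, which the tests exploit as an analytic oracle
alongside a brute-force step simulator). Ties break by lower total feature
value, then row-major index.

Open choices, resolved and documented:

* **Condition polarity.** Urban cover enters as `(1 − urban)`: a
  habitat-quality multiplier must penalize urban land. Conditions combine
  multiplicatively (per-layer weighting was equally defensible).
* **Cost transform.** `c = 1 + d`, with `d` the trailing-absence index
  (`d = 0` still present in the last period, `d = 1` absent in all
  periods; values {0, ⅓, ⅔, 1} for four periods). Raw `d` as cost would
  divide by zero for occupied cells; `c = eps + d` is available for a
  stronger cost effect. The published phrasing of the index's zero point
  ("exit in the 2000s") is ambiguous; the reading 0 = extant in the 2000s
  is consistent with "the longer absent, the harder to recover", and the
  polarity is reversible by argument.
* **Zone boundaries.** The published intervals (> 0.95; 0.95–0.9;
  0.8–0.89; < 0.8) leave 0.89–0.90 unassigned; half-open intervals at the
  stated upper bounds close the gap, so rank exactly 0.90 is Partial.
* **Polygon levels.** Mean-rank thresholds 0.90/0.80 for
  priority/important/normal are a reconstruction of "following the rule
  for nature reserves" and are configurable arguments.

## Accounting and the counterfactual

All table percentages are recomputed from stored range sizes at build
time (never cached), reported at two decimals with raw doubles preserved
in an attribute. The "mean decadal reduction" is the simple arithmetic
mean of consecutive inter-period percentages — percentages on differing
baselines, deliberately *not* a compound rate, mirroring the motivating
presentation. A self-consistency identity (baseline reduction equals the
compounding of inter-period reductions) is asserted in tests. One
published figure is internally inconsistent with its own table (the
printed 1990s-vs-1970s reduction); the package reports the recomputed
value (40.82 %) and does not reproduce the misprint.

The counterfactual projects the models of an early period (trained with
that period's human-influence layers) onto a hybrid stack: climate and
topography from one period, urban and forest from another. When the human
period equals the occurrence period — both scenarios of interest — the
training data are identical to the standard per-period fit, so the stored
ensembles are re-projected rather than refitted; the two routes coincide
by construction, and a reduction-to-identity test asserts it. A
climate-neutrality control (swapping climate on a scenario with
period-constant climate changes the range by construction not at all) and
the recovery test (counterfactual range at least the actual last-period
range in most seeds) are both in the suite.

## Numerical choices and problem sizes

* Seeds: every stochastic step derives a 32-bit sub-seed from its caller's
  seed and a stage tag; generators save and restore global RNG state.
* Tolerances: density surfaces normalized to 1 within 10⁻⁹; Schoener's D
  inputs checked to sum to 1 within 10⁻⁶; PCA loadings tested against
  closed-form eigenvectors at 10⁻⁸.
* Degenerate inputs are first-class: empty occurrence sets thin to empty;
  an empty road network makes pseudo-absence sampling fail with a message
  naming the cause; single-class training or test data are rejected; an
  all-zero feature after conditioning falls back to ranking by cost with a
  warning; an empty range reports area 0 and missing elevation.
* Test problem sizes: unit and property tests run on grids from 2 × 2 to
  60 × 60; the end-to-end recovery tests use the default 100 × 100 km
  grid with the default occurrence counts, two fast techniques (ridge
  logistic and gradient-boosted trees), 5 evaluation runs, 3 repetitions
  and 2 000 pseudo-absences per period over 10 seeds — the largest
  configuration that keeps the whole suite in a routine-CI footprint.

## Known limitations

* **Threshold-based range sizes compress early declines.** The
  TSS-maximizing cut-off tracks the *shape* of the suitability surface,
  not its absolute level. Early in the synthetic contraction, human
  pressure lowers suitability without yet reshaping its spatial ranking,
  so consecutive early-period range estimates can sit within estimator
  noise of each other even though the true occupied area has fallen; the
  estimated series then wiggles at the first step in a minority of seeds
  (the recovery test's strict-monotonicity clause fails at rates around
  0.5–0.7 across ensemble configurations, against the 0.8 asserted). The
  decline over the full series, the upslope shift, and the counterfactual
  attribution are recovered robustly. Prevalence-aware thresholding would
  likely stabilize the first step but would depart from the strict `>P`
  rule being replicated.
* The synthetic availability correction deflates absolute D values (see
  above); comparative niche statements are unaffected.
* Exact zonation is O(N²) in valid cells; fine to ~10⁵ cells, not for
  national-scale rasters without the usual speed-up heuristics.
* Real-data interfaces are plain-text (ESRI ASCII grids, GeoJSON, CSV);
  projected/geographic CRS handling is recorded but never transformed.
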
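# rangerecon

Reconstructing multi-decadal range change of an exploited mammal from
heterogeneous historical occurrence records, and turning the result into a
spatial conservation priority ranking.

The motivating system is the Chinese pangolin (*Manis pentadactyla*) in
eastern China: occurrence records compiled from gazetteers, surveys and
interviews for four decadal slices (1970s–2000s), eight environmental
layers (mean annual temperature MAT, annual precipitation MAP, frost-free
days NFFD, reference evaporation Eref, elevation, aspect, forest and urban
cover), and the question of how much of the observed contraction is
attributable to human pressure rather than climate. Because the original
occurrence database and GIS layers are not publicly deposited, the package
ships a synthetic-landscape generator with a known ground-truth
contraction, so every stage of the pipeline is testable end to end without
any download.

## What the package computes

* **Data preparation** — greedy occurrence thinning at the home-range scale
  (`d_min = max(2·√(A/π), cell)` with A = 6.97 ha), pseudo-absence sampling
  (10 000 uniform points within 15 km of roads, the region historical
  records could plausibly come from), and stepwise predictor elimination by
  variance inflation factor (`VIF_k = 1/(1−R²_k)`, threshold 10).
* **Ensemble SDM** — a registry of standard classifiers (ridge logistic,
  random forest, gradient-boosted trees, spline logistic GAM, shallow
  neural net) fitted over stratified 80/20 evaluation runs; skill scored by
  the true skill statistic `TSS = sensitivity + specificity − 1` on a
  0.01-step threshold grid; members with TSS at or above the mean retained;
  the ensemble probability binarized at the TSS-maximizing cut-off `P`
  (present ⇔ p > P); final maps a ≥ 50 % vote across repetitions.
  Per-period range size and the mean elevation of the predicted range
  follow.
* **Niche change** — PCA-env: the first two principal axes of the pooled
  standardized environments; kernel-smoothed occurrence density divided by
  availability density (occupancy `z`); Schoener's
  `D = 1 − ½·Σ|z₁ − z₂|` between each period's partial niche and the total
  niche, with a null of 100 size-matched random subsamples and p-value
  `(1 + #{D_null ≤ D_obs}) / (B + 1)`.
* **Prioritization** — core-area zonation: iteratively remove the cell with
  the smallest `max_j (w_j q_ij) / c_i` (feature fraction per unit cost,
  denominators updated after every removal), rank = removal position / N;
  condition layers `(1 − urban) · forest` degrade the 2000s probability
  input; the cost layer `c = 1 + d` grows with the trailing run of periods
  a cell has been absent; zones at rank > 0.95 / 0.90 / 0.80; polygon
  (reserve / prefecture) summaries.
* **Accounting** — percent-of-study-area, reductions vs baseline and
  between periods, mean decadal rate, zone areas, and the counterfactual
  projection (e.g. 1970s occurrences + 1970s human influence projected
  onto 2000s climate) that attributes contraction to human pressure.

## Worked example

The `analysis/` directory is a six-step narrative workflow
(`Rscript analysis/01_simulate.R` … `06_report.R`). Abridged output of a
full run (seed 1, 100 × 100 km grid):

```
True cells with suitability > 0.5 per period: 4736 3149 1797 1170
Occurrences per period: 714 561 322 117

  period range_km2 percent_of_study_area percent_reduction_vs_baseline
1  1970s      4116                 41.16                          0.00
2  1980s      4022                 40.22                          2.28
3  1990s      3363                 33.63                         18.29
4  2000s      2791                 27.91                         32.19
Mean decadal reduction: 11.89 %
Mean consensus TSS: 0.56

Zone areas (km^2):
 Mandatory Negotiated      Other    Partial
       500        500       8000       1000
Districts by level: 1 priority, 2 important, 13 normal

Counterfactual (1970s human influence, 2000s climate): 4116 km^2
Actual 2000s estimate: 2791 km^2 -> contraction attributable to human pressure
```

Reading this: the ground-truth range (cells with suitability > 0.5)
contracts 4736 → 1170 cells as the urban-pressure penalty intensifies; the
estimated range recovers the decline (4116 → 2791 km², a 32 % reduction)
and its mean elevation rises (760 → 783 m, the upslope shift). The
zonation output puts exactly 5 % / 5 % / 10 % of cells in the
Mandatory / Negotiated / Partial zones. Holding human influence at its
1970s level while imposing 2000s climate yields a counterfactual range no
smaller than the 1970s estimate — the contraction is driven by the human
term, as constructed. Ensemble skill rises over periods (TSS 0.38 → 0.88)
because later occurrences are concentrated in a sharper environmental
signal; estimates for the diffuse early-period niche are noisier, which is
the main caveat discussed in the methods vignette.

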
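---
title: "Methods: drug-effect distance, the drug atlas, and synergy prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-effect distance, the drug atlas, and synergy prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugatlas)
```

## The model in one paragraph

If two drugs show mutually exclusive sensitivity patterns across a
cell-line panel, the cellular processes they hit are presumably
independent. A cell line that happens to be sensitive to *both* drugs is
co-vulnerable: attacking its two independent survival mechanisms at once
is the setting in which more-than-additive (synergistic) killing is
expected. The package operationalizes this in three quantities per
(cell line, drug pair): the **drug distance** (how dissimilar the two
drugs' effects are over the whole panel), the **sensitivities** of that
cell line to each drug, and a **mutation-target flag** (whether either
drug targets a gene altered in that line). Larger distance, higher
sensitivity and targeting all raise the predicted probability of synergy.

## Drug distance

Each drug is represented by its vector of 1 − AUC values over the panel
(AUC is the area under the viability-versus-dose curve scaled to [0, 1],
so 1 − AUC is an effect score, high = sensitive). The dissimilarity of
two drugs is 1 minus the cosine of the angle between their effect
vectors, restricted to cell lines measured for both (default minimum
overlap 5); for non-negative vectors this lies in [0, 1]. Cosine is used
rather than correlation because effect vectors are non-negative
magnitudes and the angle, not the centered covariance, captures
"different cell lines respond".

The dissimilarity matrix is clustered hierarchically
(`cluster_drugs()`). Two linkages are exposed: `ward_d2` is the default
for distance analyses, `average` the default used for the map layout;
drug labels are sorted lexicographically before linkage so the merge set
does not depend on input row order, and missing pairwise entries are
imputed by the matrix median (logged) because linkage needs a complete
matrix. The **cophenetic distance** of two drugs is the merge height of
the lowest node joining them. By default cophenetic distances are
divided by the root height so that they live on [0, 1]; this makes them
comparable across panels and directly usable as a bounded regression
covariate. Raw heights are available with `normalize = FALSE` — whether
the distance covariate is normalized changes the slope scale, not the
fit, so both modes are exposed.

The cophenetic correlation `cophenetic_correlation()` (the Pearson
correlation between input and dendrogrammatic distances, computed
term-by-term from its defining sums) is the clustering-quality
diagnostic; values near 1 mean the tree faithfully preserves the input
distances.

Target-level distances average the cophenetic distances over all
cross pairs of drugs carrying the two targets (a target is typically hit
by several drugs), excluding pairs formed by a single drug. Pathway
analyses split pairs into same-ontology-group and different-group sets,
excluding drugs with known cross-reactivity over multiple pathways.

## The atlas layout

`layout_voronoi_treemap()` flattens the dendrogram into a tiling of a
convex container (unit circle by default; a rectangle is available) with
one convex cell per drug, cell area proportional to a per-drug weight
(uniform by default — the panel gives no principled per-drug size), and
tree-adjacent drugs in nearby regions.

The algorithm: each internal tree node splits its region between its two
children with a straight cut whose position is found by exact area
bisection. The cut direction is the principal axis of the region (plus a
small seed-derived deterministic jitter to break symmetry), so the
earliest — highest — splits claim the container's widest extent and
early-diverging branches end up at opposite ends of the map; this is how
the "place early splits toward the corners" heuristic is realized with
binary cuts. A straight cut *is* the two-site additively weighted power
diagram, so the contract (the diagram) is met while each split's areas
are exact.

A grouping threshold `b` (`branch_threshold()`: the merge height at
which the cumulative fraction of merges counted from the leaves reaches
`depth_fraction`, default 0.25 — the reference procedure leaves the
depth unstated, and 0.25 gives visually coherent groups on trees of a
few dozen drugs) defines the top-level regions. Within each group the
tiling is then smoothed by a capacity-constrained centroidal power
diagram (Lloyd moves plus additive weight adaptation with an adaptive
step; Lloyd moves are frozen once areas are close so the weights can
finish the capacity matching). The smoothed cells are accepted only when
every area is within `area_tol` (default 2%) of its target; otherwise
the exact bisection cells are kept for that group and a warning reports
the achieved tolerance. Tiling is therefore always exact to floating
point, hierarchy containment holds at the group level, and the whole
layout is deterministic given the seed.

Boundaries between adjacent cells are annotated (`border_weights()`)
with the cophenetic distance of the two drugs, so heavier lines mark
higher splits; in the SVG output stroke width is proportional to this
weight.

An exact 2D isometry of a tree metric is impossible; the map is an
overview device. The package asserts only the qualitative property that
map distance correlates positively (Spearman) with cophenetic distance.

## Sensitivity and targeting

`normalize_tissue()` centers log2 IC50 per (tissue, drug) stratum at 1:
`S = 1 + (log2 IC50 − stratum mean)`, so S < 1 is more sensitive than
the tissue average and a unit of S is a twofold concentration change.
`scale01()` min–max scales per drug over an analysis panel (0 = most
sensitive). The target flag `T` is 1 when the drug's annotated target
genes intersect the genes mutated or amplified in the cell line, 0.01
otherwise — the small positive floor keeps `log T` finite in the
closed-form score below. Amplified genes count as affected when the
annotation table lists them; the annotation is responsible for content.

`dose_response_reduce()` is a deliberately simple reduction: absolute
IC50 by log-linear interpolation of the 50% crossing and AUC as the
normalized trapezoid of viability over log2 dose. It is a documented
stand-in for four-parameter curve fitting, which is out of scope;
oscillating curves are reduced anyway but QC-flagged.

## Combination index

For n drugs with single-agent viabilities `V_k` (percent of untreated
control) and combination viability `V_comb`,

    CI = [ sum_k 1/V_k − (n − 1)/100 ] / (1 / V_comb).

CI < 0.8 is called synergy, CI in [0.8, 1] the additive band, CI > 1
antagonism. The `(n − 1)/100` correction makes the formula
scale-dependent, so fraction-scale input (all values ≤ 1) is rejected
rather than silently mis-scored. Viabilities are floored at 1% (QC
flagged) to avoid reciprocal blow-up. The **secondary CI** treats a
two-drug combination as a single agent and scores a third drug on top of
it; all three rotations are available by argument order.

`summarize_plate()` scores every combination cell of a checkerboard
against the single-agent rows/columns at matching doses and averages the
eligible cells (mean by default; median by flag). Eligibility keeps
`V_comb` within [1, 100]; the upper bound is inclusive so a fully inert
plate summarizes to CI = 1 rather than to an empty mask (lower it to 99
to drop cells indistinguishable from control). Bliss and HSA excesses
are computed alongside; the constants 7.8 (Loewe) and 2.5 (Bliss) are
stored only for interoperability with external surface-fitting output —
no Loewe surface is fit here.

## Synergy models

One row per (cell line, canonical drug pair) carries distance `d`,
sensitivities `S_a`, `S_b`, flags `T_a`, `T_b`, their maximum
`t ∈ {0.01, 1}` ("at least one drug targets a mutated gene"), an
availability flag `C` and the binary label. Strict mode (default)
requires sensitivity for both drugs; the one-drug reading is available
for the models that do not use sensitivities.

The closed-form score `theta = t e^d / (1 + t e^d)` (identically the
logistic inverse link of `d + log t`) gives a no-fit baseline, averaged
per pair over cell lines. The fitted models are logistic regressions:

* IA: `t`; IB: `t + d` (the IB − IA contrast isolates the distance);
* IIA: `t + S_a + S_b`; IIB: `t + d + S_a + S_b`.

The two sensitivity slopes are shared (a single γ): with unordered
pairs the labels of "drug i" and "drug j" are exchangeable, so separate
per-slot coefficients are unidentifiable. Fitting uses balanced negative
resampling: all positive rows are kept and an equal number of negative
rows is drawn within each tissue, repeatedly (default 1000 draws);
aggregate coefficients are means over draws. Negatives are "unknown or
not synergistic" — the balanced design is the mitigation used here, with
no positive–unlabeled correction attempted. One pooled model per draw is
the default (per-tissue fits on small strata are unstable; slope
estimates pool information while the tissue-stratified draw preserves
tissue composition); `per_tissue = TRUE` restores stratified fits,
skipping strata with fewer than 5 positives. Draws that separate
perfectly are refit with an L2 ridge of 1e-6 and counted. Under
case-control (balanced) sampling the slope estimates remain consistent;
only the intercept absorbs the sampling rate.

AUC is the exact rank statistic. Cross-validation stratifies folds by
drug pair so no pair contributes to both training and test.
`covariate_contribution()` fits all four models on the same balanced
draws and tests ΔAUC > 0 with a one-sided paired t-test over draws.
`rank_predictions()` orders candidates by predicted theta, breaking ties
toward larger distance and then lexicographically.

An earlier linear objective `C(−s·S̄ + d·D + t·ΣT)` is retained as a
diagnostic (`eq_objective()`); no loss was ever attached to it in the
source formulation, so the bounded minimizer provided here scores
squared error between its logistic transform and the label, per tissue,
and is not used for prediction.

## Synthetic data

`sim_config()` defaults: 4 processes × 8 drugs, 60 cell lines, 3
tissues, baseline vulnerability 0.3, driver-mutation rate 0.25 (with
vulnerability probability 0.95 given the matching mutation), AUC =
0.9 − 0.55 × vulnerable + N(0, 0.08), clipped to [0, 1]. These sizes
were chosen once as a panel on which the planted four-block structure
is recoverable yet noise is visible, and the full analysis runs in
seconds. Labels are drawn from the logistic mechanism
`logit θ = α + β t + δ d_true + γ (S_a + S_b)` with defaults
(−2.2, 2, 3, −1), where `d_true` is a smoothed cross-process indicator
(cross pairs uniform on [0.6, 1], within pairs on [0, 0.4]) —
`generate_labels()` stores the generating covariates and coefficients
for recovery checks. `simulate_pair_rows()` draws model rows directly
from the same logistic form with uniform covariates; this is the
parameter-recovery oracle because there the fitted covariates coincide
with the generating ones, whereas the panel route estimates distance
from the clustered responses and so attenuates slopes. Plates use
unit-slope Hill single-agent curves with twofold ladders descending
from the IC50, Bliss-product combinations times a synergy factor (0.5
for co-vulnerable cross-process pairs, 1 otherwise) and 2%
multiplicative noise; with factor 1 the mean plate CI sits near 0.94
(not exactly 1 — the CI of a Bliss-independent point is
`1 − (1 − V_a/100)(1 − V_b/100) ≤ 1`), which is the designed
interplay between the Bliss null and the 0.8 synergy threshold.

What the generator does **not** emulate: batch effects between screening
sites, dose-dependent (non-multiplicative) synergy surfaces, correlated
noise across drugs, polypharmacology (each synthetic drug hits one
process), and realistic mutation co-occurrence. Passing tests therefore
demonstrate correctness of the machinery and recoverability under the
stated mechanism, not performance on real encyclopedias.

## Numerical choices and degenerate inputs

* Linkage ties are broken by lexicographic drug order; layouts are
  deterministic given `(inputs, seed)` with RNG state restored on exit.
* Bisection cuts solve for the offset with `uniroot` at 1e-10 of the
  projection span; polygon clipping tolerance is 1e-12, border-segment
  collinearity tolerance 1e-7.
* All-zero effect vectors make the cosine undefined and error; pairs
  under the overlap minimum become missing entries with a warning.
* Constant cophenetic distances make the cophenetic correlation
  undefined (NA with warning); two constant distance sets fall back to
  a closed-form degenerate t-test branch.
* Trees whose merge heights are all equal yield that height as the
  grouping threshold, with a warning.

## Problem sizes used in the checks

The bundled checks run on the default synthetic panel (32 drugs × 60
cell lines), layouts of 2–64 cells, 200 random trees of up to 32 leaves
against a brute-force lowest-common-ancestor oracle, 100 replicate
model fits at 2000 rows each, and exhaustive clique scans on graphs of
up to 15 nodes.

## Known limitations

The distance model is purely observational: a large cophenetic distance
is evidence of independent mechanisms only insofar as the panel spans
the relevant biology. The logistic models inherit the curation bias of
their labels (absence of a report is not absence of synergy). The
layout is a visualization, not a metric embedding. The reduction of
dose-response curves is interpolation-based and will differ from
four-parameter fits near poorly sampled IC50s.
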
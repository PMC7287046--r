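# drugatlas

Rational selection of synergistic drug combinations from single-drug
dose-response data over cancer cell-line panels.

The premise: when two drugs show mutually exclusive sensitivity patterns
across many cell lines, the processes they inhibit are independent — and
a cell line sensitive to *both* drugs carries a co-vulnerability that a
combination can attack for a more-than-additive effect. `drugatlas`
turns a drug × cell-line response table into the quantities that make
this operational, for computational pharmacologists working with
pharmacogenomic encyclopedia-style data (GDSC/CCLE-like AUC or IC50
tables) or with their own screens.

## What it computes

**Drug distance.** Each drug's effect is its 1 − AUC vector over the
panel; dissimilarity is 1 − cosine of the angle between vectors
(`cosine_dissimilarity`). Hierarchical clustering (`cluster_drugs`,
Ward.D2 or average linkage) gives a dendrogram whose cophenetic
distances

&nbsp;&nbsp;&nbsp;&nbsp;*d(i, j)* = merge height of the lowest node joining drugs *i* and *j* (max-normalized to [0, 1])

are the "drug distances"; `cophenetic_correlation` reports the fidelity
of the tree to the input distances.

**The drug atlas.** `layout_voronoi_treemap` renders the dendrogram as
a Voronoi treemap: one convex cell per drug tiling a circular map, areas
weight-proportional, borders between adjacent cells weighted by their
cophenetic distance (`border_weights`); SVG/JSON output via
`write_atlas_geometry`.

**Combination index.** Checkerboard viability plates are scored with the
median-effect n-drug combination index

&nbsp;&nbsp;&nbsp;&nbsp;CI = [ Σₖ 1/Vₖ − (n − 1)/100 ] / (1 / V_comb),

with viabilities in percent of control; CI < 0.8 is synergy, ≈ 1
additive, > 1 antagonism (`combination_index`, `summarize_plate`).
`secondary_ci` scores a third drug on top of a pair treated as one
agent; Bliss and HSA excesses come along for reference.

**Synergy prediction.** Per (cell line, drug pair) the logistic models

&nbsp;&nbsp;&nbsp;&nbsp;logit θ = α + β·t + δ·d + γ·(S₁ + S₂)

combine the target flag t (1 if either drug targets a gene mutated in
the line, else 0.01), the drug distance d and tissue-normalized
sensitivities S (model variants with and without d and S isolate each
covariate's contribution). Fitting uses balanced negative resampling
within tissue (`fit_logistic`), pair-stratified cross-validated ROC/AUC
(`evaluate_auc`), and `rank_predictions` orders candidate pairs.

**Multi-drug discovery.** Pairs synergistic in enough cell lines form a
graph (`build_graph`); its triangles (or k-cliques,
`enumerate_candidates`) are multi-drug candidates, and
`dual_multi_correlation` checks that dual CIs predict the multi-drug CI.

**Synthetic ground truth.** `sim_config` / `generate_panel` /
`generate_labels` / `generate_plates` emulate all input kinds with a
planted process structure and known coefficients, so every claim above
is testable end to end.

## Worked example

```r
library(drugatlas)

cfg   <- sim_config(seed = 1)            # 4 processes x 8 drugs, 60 lines
panel <- generate_panel(cfg)
panel$response
#> response_matrix: 32 drugs x 60 cell lines ( auc ), 0 missing

d    <- cosine_dissimilarity(panel$response)
tree <- cluster_drugs(d, "ward_d2")
cophenetic_correlation(d, tree)
#> cophenetic correlation c = 0.989 over 496 pairs

lay <- layout_voronoi_treemap(cluster_drugs(d, "average"), seed = 1)
lay
#> atlas_layout: 32 cells, container area 3.138 , threshold b = 0.02468

combination_index(c(50, 50), 25)
#> CI(2 drugs) = 0.75 [synergy]

# synergy-labelled pairs sit farther apart than pairs in general
labels <- generate_labels(panel, cfg)
cm  <- cophenetic_distance(tree)
pos <- labels[labels$label == 1, ]
compare_distance_sets(cm[cbind(pos$drug_a, pos$drug_b)],
                      cm[cbind(labels$drug_a, labels$drug_b)])
#> t_one_sided: synergy (n=12209, mean=0.887) vs reference (n=29760, mean=0.76)
#>   | stat = 37.9, p = 5.93e-308

# coefficient recovery on rows drawn from the model itself
rows <- simulate_pair_rows(2000, alpha = -1.5, beta = 2, delta = 3,
                           gamma = -1, seed = 2)
fit <- fit_logistic(rows, "IIB", n_resamples = 50, seed = 3)
fit
#> logistic_fit model IIB ( 50 resamples )
#> (Intercept)           t           d       s_sum
#>      -1.307       2.072       2.999      -1.244
evaluate_auc(fit, rows, "cv_kfold", seed = 4, n_resamples = 10)$auc
#> [1] 0.813
```

The cophenetic correlation near 1 says the dendrogram preserves the
cosine distances almost perfectly on this low-noise panel. The
distance comparison reproduces the expected pattern — labelled
synergistic pairs average a distance of 0.89 against 0.76 overall. The
fitted slopes (2.07, 3.00, −1.24) recover the generating (2, 3, −1),
and the pair-stratified cross-validated AUC of 0.81 is what that
mechanism supports at this sample size.

A command-line wrapper over the same functions ships in
`inst/cli/drugatlas.R` (`simulate`, `distances`, `build-atlas`,
`score-ci`, `fit-model`, `report`).

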
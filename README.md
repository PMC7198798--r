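# immunet

Directed, signed immune-signaling networks from short plasma cytokine time
courses collected around a maximal exercise challenge.

## The problem

A graded exercise test to VO2 max is a standardized provocation of immune
signaling: 16 plasma cytokines are drawn at rest, during exercise, at peak
effort, and through a 4-hour recovery (8 draws in all), in two subject
groups — healthy controls (HC) and an ill group (GWI, Gulf War Illness).
Chronic multi-symptom illness often shows up not as different cytokine
*levels* but as different *wiring*: which mediators drive which during the
return to rest. `immunet` is for researchers who want to infer that wiring
per subject, compare it between groups, check it against documented immune
signaling, and ask which receptor blockades would re-align an ill circuit
with a healthy one.

## The model

Cytokines are aggregated into 9 functional sets (MK1A, MK1B, MK2, MK6,
MK15, MK23, CK1, CK2, CK17) by pooled principal components of log2
fold-change trajectories. Each subject's recovery is then fitted with a
linear rate equation

    dx_i/dt = sum_j a_ij x_j        (X' = A X)

where `a_ij` is the signed influence of source node `j` on the rate of
change of target node `i` (positive = activation, negative = inhibition,
zero = no interaction). `A` is estimated by multivariate partial least
squares regression of finite-difference rates on scores, with the number
of latent components chosen by a broken-stick rule
(`b_k = (1/p) sum_{i=k..p} 1/i`) and coefficients pruned to discrete
edges. Downstream analyses operate on the estimated networks: resampled
consensus and unanimity "characteristic" circuits, weighted graph edit
distance `sum_ij |a_ij - b_ij|` with resampled significance, centralities
and hub/authority scores, feedforward/feedback motif classification,
exhaustive single and paired in-silico receptor blockade search, and
qualitative fuzzy-logic dynamics simulation. A synthetic two-group cohort
generator with known ground-truth networks backs every stage with
recovery tests.

## Worked example

Generate a synthetic cohort at the protocol scale and run the full
analysis under one seed:

```r
library(immunet)

report <- run_pipeline(pipeline_config(seed = 7))
print(report)
#> <pipeline_report>
#>   cohort: 11 HC + 12 GWI subjects, 2944 records
#>   divergence: 16 cytokines, 7 with ranksum p < 0.05
#>   GED inter 0.0953 vs pooled intra 0.0232 (ranksum p 0)
#>   characteristic edges: HC 4, GWI 2
#>   best blockade: {CK17,MK23} GED 0.0429 (38.9% reduction)
```

Reading the numbers: 7 of 16 cytokines show significant inter-group
divergence of their recovery trajectories (subject-permutation rank-sum
test); the mean normalized graph edit distance *between* the groups'
consensus circuits (0.0953) far exceeds the pooled distance *within*
groups (0.0232), so the two cohorts carry genuinely different circuitry
(they were generated from distinct ground-truth networks); unanimity
across 100 subject subsamples leaves small characteristic circuits; and
of the 45 possible single/paired blockades, jointly silencing CK17 and
MK23 moves the ill circuit 38.9% of the way toward the healthy one by
edit distance.

The pieces compose individually as well:

```r
cohort <- emit_cohort(synthetic_cohort_spec(seed = 42))
series <- preprocess_panel(cohort$panel)     # non-detects, 3-min grid,
                                             # fold change, recovery slice
model  <- fit_pooled_pca(series)             # pooled coordinate system
scores <- score_aggregates(series, model)

net <- fit_rate_network(scores[["HC01"]])
summary(net)
#> Rate network for HC01 (HC)
#>   latent components retained: 5 (variance fractions 0.558, 0.223, ...)
#>   edges: 26 (15 activating, 11 inhibiting)
#>   rate-fit RMSE: 0.003671 per minute
```

`fit_rate_network()` returns a classed model object with `print`,
`summary`, `coef` (the adjacency matrix), `predict` (rates), `residuals`,
`simulate` (trajectories from the fitted matrix), and `plot` (signed
digraph) methods. `divergence_table()`, `consensus_ensemble()`,
`ged_significance()`, `node_centralities()`, `classify_ffls()`,
`rank_blockades()`, `simulate_scenarios()` and `rescue_score()` cover the
downstream stages; `reference_network()` loads the packaged synthetic
9-node literature-style reference edge list.

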
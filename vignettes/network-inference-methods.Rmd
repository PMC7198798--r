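---
title: "Inferring directed cytokine signaling circuits from exercise recovery time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring directed cytokine signaling circuits from exercise recovery time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunet)
```

## The problem

A maximal graded exercise test is a standardized whole-body provocation of
immune signaling: plasma cytokines are drawn at rest, during exercise, at
peak effort (VO2 max), and through a 4-hour recovery. Two groups — healthy
controls (HC) and a chronically ill group (GWI, Gulf War Illness) — may
reach similar peaks yet *recover* differently. The working hypothesis is
that the difference lives less in the individual marker levels than in the
wiring: which mediators drive which during the return to rest. `immunet`
turns panels of 16 plasma cytokines sampled at 8 draws into per-subject
directed, signed networks over 9 functional cytokine sets, and then asks
three questions: do the group circuits differ (topological comparison), how
do they relate to documented immune signaling (concordance with a reference
network), and which receptor blockades would make the ill circuit most
resemble the healthy one (in-silico intervention, followed by qualitative
dynamics simulation).

## The model

The core model is a linear rate equation on the aggregate activation
scores $x_1, \dots, x_9$:

$$\frac{dx_i}{dt} = \sum_{j=1}^{n} a_{ij}\, x_j,
\qquad \dot X = A X,$$

where $a_{ij}$ is the signed influence of source node $j$ on the rate of
change of target node $i$: positive means activation, negative inhibition,
zero no interaction. Everything downstream — edit distances, consensus,
motifs, blockades — operates on the estimated $A$ matrices, always in this
"rows are targets, columns are sources" orientation.

## Preprocessing chain

1. **Non-detect replacement.** Assay zeros are replaced by the smallest
   detectable concentration of that cytokine anywhere in the cohort (both
   groups pooled). The operation is idempotent; a cytokine with no
   detectable value anywhere is an error rather than a silent guess.
2. **Uniform interpolation.** Each subject-by-cytokine series is linearly
   interpolated to a 3-minute grid (the minimum sampling interval of the
   draw schedule), from its first to its last observation — never beyond.
3. **Fold-change normalization.** Values are divided by the geometric mean
   of the healthy resting (T0) concentrations of that cytokine, i.e.
   $2^{\log_2 v - \overline{\log_2 v_{\mathrm{HC,T0}}}}$. The baseline uses
   the raw T0 observations, not interpolated values; the interpolation grid
   rarely falls exactly on every draw, and the resting draw deserves to
   enter the baseline untouched.
4. **Recovery slicing.** The analysis window is $[0, 240]$ minutes from
   peak effort — 81 grid points covering 6 of the 8 draws. Subjects whose
   last draw falls slightly earlier are kept as-is (no extrapolation).

Outlier handling is an explicit exclusion list (`exclude_subjects`), not an
automatic rule: the field practice is to remove subjects with out-of-range
expression after inspection, and no numeric criterion generalizes safely.

## Aggregation into functional sets

The 16 cytokines map onto 9 functional sets by predominant cell of origin
and mode of action: monokine sets MK1A/MK1B (IL-1a, IL-1b, IL-8, IL-12 —
one shared block scored twice), MK2 (IL-10), MK6 (IL-6), MK15 (IL-15),
MK23 (IL-23), and lymphokine sets CK1 (IL-2, IFNg, TNFa, TNFb), CK2 (IL-4,
IL-5, IL-13), CK17 (IL-17). Multi-cytokine sets are scored by principal
components of the mean-centered log2 fold-change block pooled over **all**
subjects of **both** groups and all recovery time points — one common
coordinate system, so that networks of different groups are comparable
edge for edge. Centering without variance scaling is deliberate:
fold-change already places cytokines on a shared scale, and scaling would
let assay noise in flat cytokines dominate a block.

A second component is retained only when PC1 explains less than 80% of a
block's variance; on the original panel this rule splits exactly one
block, MK1, into the MK1A/MK1B pair. The package's default layout
(`layout = "fixed"`) hard-wires that outcome so the node universe is always
the canonical 9 — the reference network and every downstream comparison
assume it — while `layout = "auto"` applies the bare threshold rule for
diagnostics. PCA signs are arbitrary, so each component is flipped to make
its largest-magnitude loading positive, identically for both groups.

## Divergence of individual cytokine trajectories

Before any network is fit, per-cytokine divergence between subjects is
quantified by a time-series semi-metric. The packaged default ("envelope"
distance) linearly re-interpolates both curves on the union of their grids
over the overlapping time span and divides the mean absolute difference by
the joint envelope range (global maximum minus global minimum of the two
curves). This is 0 exactly when the curves coincide, symmetric, bounded in
$[0,1]$, and indifferent to unequal lengths; the triangle inequality is
*not* guaranteed, and not needed. A normalized dynamic-time-warping
variant is available under the same contract, and the distance is a
pluggable strategy so a different semi-metric can be dropped in.

The resampling design mirrors the study protocol: per repeat, 11 random
subsets of 10 subjects per group (leave-one-out at $n = 11$, leave-two-out
at $n = 12$); within each paired subset all intra-group pairwise distances
and all $10 \times 10$ cross-group distances are accumulated; 11 repeats.
These lists (sizes $11 \times 45$ and $11 \times 100$ per repeat) are the
summary-statistic surface — means, SEs, medians, MADMs.

For the *hypothesis test* the package deliberately departs from applying a
two-sample test to those lists. Each resampled list repeats every
underlying subject pair many times, and even the unique pairwise distances
are dependent (two pairs share a subject). Measured on shared-truth null
cohorts, the asymptotic rank-sum test is badly mis-calibrated on the
resampled lists and mildly conservative on the unique pairs. The shipped
test therefore keeps the rank-sum statistic but refers it to its
subject-label permutation distribution (a Mantel-type test): group labels
are permuted over subjects, the pair classification (within/between) is
recomputed, and a two-sided permutation p-value is returned. Under
exchangeability of subjects this is exact by construction; 400
permutations with a fixed seed keep it deterministic and resolve p down to
about 0.0025.

## Network inference

Rates are estimated by central finite differences on the 3-minute grid
(one-sided at the window edges), and all nine rate rows are regressed
jointly on all nine score rows in one multivariate partial least squares
(NIPALS PLS2) fit per subject, with predictors standardized and
coefficients back-transformed to the original scale. The number of latent
components $K$ is chosen by a broken-stick rule on the predictor-variance
fractions: component $k$ survives while its fraction exceeds
$\lambda\, b_k$, with $b_k = \frac{1}{p} \sum_{i=k}^{p} \frac{1}{i}$ the
expected fragment sizes of a randomly broken unit stick.

Two parameters matter and both are calibrated rather than assumed:

* **$\lambda$ (broken-stick scale, default 0.01).** The textbook stick
  ($\lambda = 1$) is a noise guard for flat eigenvalue spectra. Smooth
  interpolated trajectories are nothing like that: their variance
  concentrates overwhelmingly in one slow mode (typical fractions
  $0.94, 0.05, 0.002, \dots$ against thresholds $0.31, 0.20, \dots$), so
  $\lambda = 1$ always retains a single component and the fit degenerates
  to rank one regardless of how informative the data are. Small $\lambda$
  lets genuinely informative low-variance components in while the stick
  still cuts off the numerical noise floor.
* **$\theta$ (pruning threshold, default 0.2).** Coefficients smaller in
  magnitude than $\theta$ times the largest off-diagonal coefficient are
  zeroed to produce discrete signed edges; the diagonal (self-degradation)
  is always fitted but never scored as an edge.

The defaults were fixed once by calibrating on the package's own synthetic
benchmark — maximizing mean edge F-score against known generating networks
— which is the same procedure the method uses in the field, where the
broken-stick parameters are tuned against a literature-based reference
network by constrained simulated annealing. That calibration is available
as `calibrate_inference()` (geometric cooling 0.95, 200 iterations by
default, box constraints $\lambda \in [10^{-3}, 0.1]$,
$\theta \in [0, 0.5]$, deterministic objective, reproducible from a seed).

An orientation guard is tested end to end: simulating from a fitted $A$
reproduces the fitted rates, which catches transposition bugs in a single
assertion.

## What the synthetic cohort emulates — and what it cannot

The generator produces two-group panels from known ground-truth networks,
so every downstream stage has a recovery surface. Its study conditions are
fixed defaults, not dials: 11 HC + 12 GWI subjects; 16 cytokines at the 8
protocol draws with ±1 min sampling jitter; lognormal measurement noise
with $\mathrm{sd}(\log\,\mathrm{conc}) = 0.1$, matching the assay's
documented intra-assay variability of about 0.09–0.20; detection floors
censoring to zero; per-subject edge-weight jitter (lognormal, sd 0.1) and
5% edge dropout around the group network.

The ground-truth networks deserve the longest explanation. A stable
matrix drawn with independent random signs relaxes monotonically, and a
single relaxation observed at 81 points is *not persistently exciting*:
its numerical rank is about 6, so the action of $A$ on the unexcited
subspace is unidentifiable — no estimator can recover such a network from
one trajectory, at any noise level (driving the system with process noise
does not help: both the excitation and the finite-difference noise scale
with the same $\sigma$, leaving the error per coefficient at the size of
the edges themselves). The default generator therefore draws reciprocal
activator–inhibitor pairs — with probability `density` a node pair gets a
sign-opposed edge couple — on top of weak, heterogeneous per-node
self-degradation, stabilized by a spectral shift. The dynamics are weakly
damped coupled oscillations whose modes persist across the 4-hour window
(periods roughly 35–160 min at the default weight scale of 0.07/min),
which both makes the inference problem well-posed and mirrors the
oscillatory within-session cytokine responses that this exercise protocol
is known to produce. The independent-sign construction remains available
(`structure = "independent"`) precisely to demonstrate the difference.

Integration is Euler–Maruyama with internal substeps of at most 0.25 min;
at the bare 3-min grid step the Euler map amplifies oscillatory modes
($|1 + h\lambda| > 1$) and distorts the process it is supposed to produce.
With zero noise the integrator matches the matrix-exponential solution to
the tolerance the tests assert.

What passing recovery tests on this generator shows: the estimator,
aggregation and consensus machinery are correct, orientation is preserved,
and accuracy degrades gracefully with measurement noise. What they cannot
show: that real recovery dynamics are linear, that real cytokine noise is
lognormal and independent across draws, or that the real cohort's dynamics
are as persistently exciting as the synthetic ones — on strongly
overdamped real data the inferred circuits should be read as the
identifiable projection of the true wiring, not its entirety.

## Consensus, comparison, intervention, dynamics

**Consensus.** Subject networks are inferred once (a subject's fit does
not depend on the subsample) and 100 subject subsamples of 10 are scored:
within a subsample an edge survives if at least 6 of 10 subject networks
carry it in the same direction; the sign is the majority among supporters
(an exact tie drops the edge) and the weight the median magnitude among
majority-sign supporters. The characteristic circuit of a group is the
unanimity network — edges present in all 100 consensus networks. Edge
counts are provably monotone non-increasing along
per-subject-union → majority → unanimity.

**Comparison.** The weighted graph edit distance between two circuits is
$\sum_{i \ne j} |a_{ij} - b_{ij}|$. The default normalizes each matrix by
its largest off-diagonal magnitude and divides by $N(N-1)$, making values
comparable across networks of different weight scales; raw mode preserves
the literal edit-cost sum. Significance of group separation is assessed by
two-sample tests of inter-group vs pooled intra-group pairwise GEDs.
Centralities use edge length $1/|w|$ for path metrics, betweenness
normalized by $(N-1)(N-2)$, *unnormalized* harmonic in/out-closeness
(values above 1 are meaningful), and L1-normalized HITS hub/authority
scores. Feedforward loops are typed by the standard coherent/incoherent
sign-triple table (C1 $(+,+,+)$, C2 $(-,+,-)$, C3 $(+,-,-)$, C4
$(-,-,+)$; I1 $(+,-,+)$, I2 $(-,+,+)$, I3 $(+,+,-)$, I4 $(-,-,-)$), kept
in one table so a convention correction never touches logic; feedback
loops up to length 3 are labeled by the product of their edge signs.

**Intervention.** A receptor blockade of node $k$ zeroes the off-diagonal
of column $k$ — the node stops signaling but can still be regulated; its
self-degradation stays. All 9 single and 36 paired blockades (plus the
no-blockade baseline) are evaluated exhaustively by mean GED from the
edited ill circuit to the healthy target, with ties broken
lexicographically; for ensembles the mean and standard error are taken
over the full cross product of pairs.

**Dynamics.** A qualitative fuzzy-logic engine simulates circuit response:
a node's target state is the fuzzy OR (max) of its activators' normalized
weighted states, attenuated by AND-NOT of the inhibitor envelope
($a (1-h)$); a node with no activators rests at basal. States advance by
$x \leftarrow x + (\Delta t/\tau_i)(\sigma_s(\mathrm{target}) - x)$,
where $\sigma_s$ is a logistic reshaping centered at 0.5 (steepness
$s = 8$ by default) and $\tau_i$ are per-node time constants drawn
truncated-positive Gaussian (mean 10, sd 2 steps) per run; 100 runs over
100 steps by default, all states clamped to $[0,1]$. Source (ill), target
(healthy) and treated (blockade-edited) circuits are simulated under
*identical* sampled parameters per run, so scenario differences reflect
topology alone. The per-node rescue score
$r = 1 - \mathrm{RMS}(\mathrm{treated} - \mathrm{target}) /
\mathrm{RMS}(\mathrm{source} - \mathrm{target})$ reads 1 for a perfect
rescue, 0 for no change, negative for a worsening.

## Numerical choices and degenerate inputs

* Derivatives: central differences, exact for locally linear signals; the
  window edges use one-sided differences.
* PLS: NIPALS with deflation, tolerance $10^{-10}$; in the full-rank limit
  the coefficients equal ordinary least squares (asserted against `lm()`).
* Sign ties: a consensus edge supported by equally many positive and
  negative weights is dropped and logged; an aggregate edge assembled from
  equal-confidence opposite-sign sources is kept with sign `NA`
  ("ambiguous") and excluded from sign-sensitive scoring.
* Empty networks: pruning an all-zero matrix warns and returns the empty
  network; HITS on an edgeless graph warns and returns zeros; an empty
  inferred network reports PPV 0 with an explicit flag.
* Randomness: every stochastic routine takes a seed, restores the global
  RNG state on exit, and derives sub-seeds by a fixed counter scheme, so
  the pipeline is reproducible from a single master seed and any stage can
  be re-run in isolation.

## Problem sizes used in validation

The shipped validation runs are sized for quick, repeated execution: the
structure-recovery study uses 12–20 generator seeds with two subjects per
seed at three noise levels; null-calibration studies use 25–50 shared-truth
cohorts at the full 11 + 12 protocol scale; the end-to-end pipeline runs at
the full protocol scale with 100 consensus subsamples. These sizes are the
package's own validation design; all of them are plain parameters and scale
up freely.

## Known limitations

* The linear rate model is a first-order description; saturating or
  delayed regulation is out of scope by design.
* The packaged 9-node reference network is a clearly labeled synthetic
  stand-in with field-plausible polarity, not a curated import; the
  construction tools (cell-node collapse, confidence filtering, union
  merging) are what the package warrants, and they accept any edge table.
* The aggregate-level MK1A/MK1B split shares four cytokines between two
  nodes; at aggregate level any edge incident to the block is propagated
  to both nodes, so MK1A-vs-MK1B asymmetries are only meaningful in the
  data-derived circuits, never in the reference.
* Per-subject inference quality is bounded by identifiability of a single
  recovery trajectory; consensus over subjects and subsamples, not the
  individual fit, is the unit of interpretation.
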
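---
title: "Methods: maze exploration metrics, simulation, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maze exploration metrics, simulation, and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazexplore)
```

This vignette is the package's own account of its models and numerical
choices: what each piece assumes, which knobs matter, and what passing the
test suite does and does not establish about real behavioral data.

## The maze as configuration

All metrics and statistics are maze-agnostic: a maze is any connected,
undirected labeled graph of decision points (target objects vs hallway
junctions) with positive edge lengths in virtual units, supplied as
GraphML or JSON. The package ships `default_maze()` — 26 locations A–Z on
a grid, 9 target objects placed mostly on low-degree nodes (alcoves and
dead ends, where objects plausibly sit in a hedge maze), 36 axis-aligned
edges of 3 or 6 units, degrees ≤ 4, four painting-adjacent junctions.
The layout of the original task environment is not published in
machine-readable form; any maze with the same interface can be dropped in
as a file, and nothing downstream changes. Paintings are node attributes
only (visual landmarks for a human navigator); they are never trajectory
states.

Travel time between locations uses the task's movement constants —
1 unit/s translation, 1 s per 90° rotation — and is computed by Dijkstra
on a directed-edge state expansion, so heading changes along a route are
costed exactly. Two conventions are worth stating:

* the initial heading is free (a traveler may orient before starting),
  which makes travel time symmetric in its endpoints;
* as a consequence, concatenating two optimal legs at a via-point can
  cost up to one extra about-face (2 s), so the triangle inequality holds
  with that 2 s slack rather than exactly.

Turn-aware routing requires node coordinates (shipped with the default
maze); the grid layout also defines the 0/90/180/270° headings used by
the event logs.

## Visit coding and the ten measures

A block's trajectory is coded as the sequence of visited letters, starting
with the placement location; a left/right press repeats the current
letter, and maximal runs of equal letters collapse to one visit. Blocks
are never concatenated across the boundary: participants are re-placed
between blocks, so no transition, repeat-collapse, or hallway run spans
it. Pooled scores are sums (counts, distance, time), pooled-count
functionals (entropy, clustering), or maxima over blocks (longest hallway
sequence).

Choices that were genuinely open:

* **Entropy bins.** All maze locations are bins, with empty bins
  contributing 0 via the `p ln p` limit; natural logarithm. The value is
  identical if only visited bins are used — only the theoretical bound
  `ln n` depends on the convention.
* **Clustering.** The "clustering of exploration" measures are the sample
  standard deviation (denominator n − 1) of visit counts across all nodes
  of one kind, zero-visit nodes included. This matches the stated
  direction (higher SD = more clustered visits) and a worked case: nine
  targets with counts (9, 0, …, 0) give SD 3.
* **Pause accounting.** Pause duration is idle time: for each press, the
  gap between the press and the moment the previous action finished
  (rotation 1 s/90°, travel = edge length in seconds), plus the terminal
  wait. Under this accounting dwell + rotation + travel exactly exhausts
  the 480 s block, which is what a physical replay of the key log
  implies. The alternative — counting rotation time as pause — changes
  only the split between `pause_duration` and `turns_made` seconds.
* **Bare strings.** Without timestamps, turns are inferred as one per
  consecutive repeat beyond the first and presses as letters minus one;
  these are exact for well-formed logs. Pause duration is then
  *unavailable* and raises an error rather than returning 0.

## The cohort simulator

The simulator exists to give the pipeline data with the statistical
structure the analysis assumes — group mean contrasts of realistic size,
between-participant heterogeneity, and a test-phase outcome mechanically
linked to exploration — not to model cognition. An agent at a decision
point pauses (exponential dwell), then draws a neighbor with weight
`exp(−revisit_aversion · recency)`, where recency decays geometrically
(factor 0.9 per decision) since the last visit; with probability
`target_bias` it instead steps along the shortest path toward the
least-recently-seen target object it has already discovered. Rotations
and travel consume real time inside the 480 s budget, so slower agents
simply do less.

Test-phase knowledge is the set of traversed edges, each retained with
probability `1 − knowledge_decay`; a trial succeeds iff the known
subgraph contains a route within the 45 s budget including turn costs.
This operationalizes wayfinding success as spatial graph knowledge —
reachability in a partially known graph — which is exactly the construct
the test phase is meant to measure. Start/goal pairs are drawn uniformly
without replacement from the 72 ordered target pairs, since the original
trial schedule is not published.

Default group profiles (dwell 1.25 s vs 1.75 s; target bias 0.10 vs 0.38;
knowledge decay 0.25 vs 0.50; shared revisit aversion 1.5) were fixed
once so that, at study sizes (50 young, 87 midlife; sex ratios 26/50 and
64/87; ages uniform in 18–28 and 43–61), the seven qualitative group
contrasts hold — midlife: less distance, longer pauses, fewer presses,
more object visits, fewer hallway visits, shorter hallway runs, lower
success, with midlife success sitting at the 1/9 chance level — and the
per-block magnitudes (distance in the mid-200s of units, pauses around
two minutes, entropy near 3.0) are of realistic size. Between-participant
heterogeneity enters through an individual gamma-distributed dwell mean
(CV 0.3) and truncated-normal jitter on bias (SD 0.06) and decay
(SD 0.10). All randomness flows from one master seed through
per-participant substreams, so any participant is reproducible in
isolation.

What the simulator deliberately does not emulate: view-based navigation,
landmark use (paintings are inert), memory consolidation between blocks,
or any fit to the original participants. Passing tests on simulated
cohorts therefore validates the *pipeline* — coding, metrics, and the
statistical machinery — not claims about human midlife exploration.

## Statistical choices

* **Transforms.** Skew-guided: |g₁| ≤ 0.5 none, ≤ 1 square root, ≤ 2 log,
  > 2 inverse; negative skew is reflected (max + 1 − x) first and
  nonpositive values are shifted before log/inverse. The thresholds are
  the package's convention; the transform applied is always recorded, and
  group directions are reported on the raw scale (reflection and the
  inverse each reverse order).
* **ANCOVA.** `variable ~ group + sex`; the group term is tested adjusted
  for sex (with no interaction, type II and III coincide);
  η²ₚ = SS_group / (SS_group + SS_res). No multiplicity correction is
  applied across the eleven variables, mirroring common practice in this
  design; readers should treat the per-variable p-values accordingly.
* **Block effects.** Random-intercept model per group with Satterthwaite
  denominator degrees of freedom (lmerTest); η²ₚ from the F statistic via
  `F·df1/(F·df1 + df2)`.
* **Rank-sum vs chance.** The observed success vector is compared with an
  equal-length constant vector at 0.11 (mid-ranked ties); the statistic is
  the Mann–Whitney U of the observed sample. With ≤ 20 pooled values the
  p-value is exact by enumeration; otherwise a normal approximation with
  tie and continuity corrections (identical to `wilcox.test` with
  `exact = FALSE`). A constant-vector comparison is used because a
  one-sample signed-rank statistic cannot exceed n(n+1)/2, which is
  inconsistent with the magnitude such studies report at n = 50.
* **Chi-square.** Yates-corrected 2×2 test of independence (the corrected
  statistic is what studies of this design conventionally print).
* **Mediation.** Linear, no-interaction product-of-coefficients: ACME =
  a·b from `M ~ X` and `Y ~ X + M`; the total effect equals ACME + ADE by
  construction. Uncertainty by nonparametric percentile bootstrap
  (participants resampled, B = 999 default) — a simpler estimator with
  the same target as quasi-Bayesian draws in linear models. Age enters in
  years, continuously; sex adjustment is available behind a flag but off
  by default. Verified property: 95% intervals cover a known ACME in
  92–98% of 500 simulations at n = 200.
* **PCA.** Correlation-matrix PCA (the measures have incommensurate
  units). Deterministic sign convention: each loading column's dominant
  entry is positive. Permutation significance shuffles every column
  independently (B = 999 default); components are retained sequentially —
  a PC counts as significant only if it and every earlier PC exceed the
  1 − α quantile of their rank-matched permuted variance shares. The
  sequential rule matters: testing all ten PCs marginally at α = 0.05
  would flag at least one spurious PC in roughly 40% of pure-noise
  datasets, while the sequential version holds the familywise null rate
  at PC1's 5%. Loadings are tested position-wise against permuted
  |loading| quantiles, and interpretation additionally applies the strict
  |0.4| cutoff. PC3 is oriented so the longest-hallway-sequence loading
  is positive (higher = more edge exploration), and the flip is recorded.
  Per-group regressions reuse the pooled-fit scores.
* **Classifiers.** Logistic age-group models; the combined exploration
  model drops PCs with Wald p ≥ 0.05 and refits. ROC/AUC via the
  Mann–Whitney identity with mid-rank ties; DeLong's paired test via
  structural components, with the self-comparison defined as p = 1.
  Quasi-separation (diverging coefficients) is an explicit error naming
  the predictor, which small strongly-contrasted cohorts can trigger.

## Problem sizes and determinism

The test suite exercises the oracles at the sizes the package commits to:
1,000 random sequences for the entropy and hallway-run oracles, 500
random ROC instances, 1,000 null cohorts of 30 + 30 for the ANCOVA size
check, 50 runs at B = 999 for the permutation-PCA null, and 500
mediation simulations at n = 200 for bootstrap coverage. Pipeline runs
are deterministic given the configuration: identical config + seed yields
byte-identical numeric tables, and the run manifest records everything
needed to reproduce them.

## Known limitations

* The default maze is a plausible stand-in, not the original layout;
  absolute metric values (especially object-visit counts, which scale
  with target-node degree) depend on it.
* The simulator's success mechanism is reachability in a remembered
  subgraph; it cannot produce dissociations between graph knowledge and
  other spatial representations (route or survey knowledge).
* Real key logs may contain hesitations, aborted turns, or clock jitter
  that the replay accounting attributes to pauses.
* The per-position permuted-loading test is conservative for components
  spread over many variables: a factor loading k variables equally has
  loadings near 1/√k, which for k ≳ 4 falls below the Haar-random
  loading quantile even when the component itself is clearly significant.
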
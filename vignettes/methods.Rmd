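---
title: "Methods: evaluating prediction submissions and recovering optimal recipes in a feature morphospace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating prediction submissions and recovering optimal recipes in a feature morphospace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(morphobench)
```

## Overview

morphobench analyses the output of a multi-team outcome-prediction
benchmark: a validation cohort with observed one-year post-stroke scores,
and a set of submissions, each carrying (a) predicted scores for every
validation patient and (b) a declared binary combination of 9 inputs and 8
method classes (17 features in the canonical order of
`morpho_features()`). The pipeline ranks submissions, embeds their feature
combinations into a discretized 2-D morphospace, localizes
performance-associated regions with permutation t-maps, and inverts
significant local maxima into binarized "optimal recipe" feature
combinations per outcome domain. A synthetic generator emulates the study
conditions so the full pipeline is testable without the restricted
clinical data.

## Evaluation metrics

* **R²** is the squared Pearson correlation `cor(pred, truth)^2`. We follow
  the benchmark convention of reading "Pearson mean R²" literally as
  squared correlation rather than the coefficient of determination
  `1 − SS_res/SS_tot`; the two differ for biased predictions (a submission
  can rank patients well while being miscalibrated), and the squared
  correlation rewards ranking. Constant predictions return 0 with a
  `degenerate` flag instead of failing, so trivial submissions remain
  rankable. The leaderboard metric is the arithmetic mean of R² over the
  six main scores (FM motor, FM total, MoCA, IST, HAD-A, HAD-D); note this
  weights the Fugl-Meyer instrument twice, which we keep as printed in the
  source convention. Ties are broken by lower mean MSE, then submission id.
* **MSE / MAE** are plain means of squared/absolute differences, in squared
  score units / score units.
* **AUC** uses the Mann–Whitney rank formulation — the probability that a
  randomly chosen truly-poor patient receives a more poor-leaning
  prediction than a good one, ties counted 1/2 — after orienting
  predictions by each score's poor direction (low values lean poor for FM,
  MoCA and IST; high values for HAD-A/HAD-D). Poor outcomes use the
  clinically validated thresholds FM ≤ 100, MoCA ≤ 25, IST ≤ 28,
  HAD-A ≥ 8, HAD-D ≥ 8, boundaries included. When the validation sample
  contains a single class the AUC is undefined and reported `NA`; this
  happens systematically for FM total in simulated cohorts, whose one-year
  marginal lies several SD above the threshold.

## Morphospace

The submission-by-feature binary matrix is embedded with UMAP (`uwot`),
Hamming metric, `n_neighbors = min(15, n − 1)`, `min_dist = 0.1`, fixed
seed; with a single thread and deterministic SGD the layout is
bit-reproducible. The Hamming metric makes proximity mean "shared design
choices", and only the 17 feature bits enter the embedding — per-score
performance is used exclusively as the statistical signal downstream, so
the geometry cannot leak the outcome. (A per-score embedding that appends
performance columns is deliberately not the default for this reason.)

The layout is discretized onto a 60×60 grid by per-axis min–max scaling to
[0, 59] with half-up rounding; the axis bounds are retained so any cell
maps back to a continuous coordinate (its center). Coordinates are reported
0-based as (gx, gy). A degenerate axis collapses to the middle cell with a
warning.

**Inverse transform.** UMAP has no analytic inverse here, so the inverse is
defined as the inverse-distance-weighted (1/d, k = 5) average of the
nearest training submissions in embedding space. At a submission's own cell
the weights are dominated by that submission, so binarizing at 0.5
reproduces its feature row on well-separated designs; between clusters the
inverse interpolates. Round-trip fidelity is the conformance property the
test suite checks (block-structured designs, ≥ 90% per-feature agreement).
Because UMAP's repulsive layout keeps even identical rows a small distance
apart, duplicate submissions land *near*, not *on*, each other; the
meaningful invariant (duplicates closer than non-duplicates) is what we
test.

## Permutation t-maps

For each outcome, each submission contributes a Gaussian "presence" bump
(unit peak, width `sigma = 2` cells by default, chosen to bridge
neighboring cells without blurring distinct approaches; kernel tails below
1e-12 are clamped to exact zero to avoid underflow artifacts at remote
cells). At each cell the statistic is the slope t from the simple linear
regression of the n per-submission R² values on their n presence values;
cells with zero presence variance get t = 0. The null is built by permuting
the R² vector across submissions (submissions are treated as exchangeable
units; a team-blocked permutation could be added but the benchmark pools
all submissions), and family-wise error over the 3600 cells is controlled
with the maximum-statistic method: the corrected p-value of a cell is the
add-one proportion of permutations whose grid-wide maximum t reaches its
observed t, so p ≥ 1/(n_perm + 1). Inference is one-sided for positive
association. Defaults: `n_perm = 5000`, `alpha = 0.05`.

Significant cells are segmented into 8-connected clusters (ordered by size,
then scan position), each contributing its local t-maximum; plateau ties
resolve to the first cell in scan order (increasing gy, then gx). Under an
exchangeable null the family-wise false-positive rate sits at the nominal
0.05 (verified by simulation in the test suite, 200 repetitions × 1000
permutations).

## Recipes

Every grid-cell center is inverted to a continuous 17-vector and binarized
at 0.5 (boundary included — a value exactly at threshold counts as
present). Reading the binary stack at a cluster's local maximum gives that
cluster's recipe; different clusters of the same score may carry different
recipes, reflecting that more than one approach can predict an outcome
comparably. The per-domain table keeps, for each of motor
({FM total, FM motor}), cognitive ({MoCA, its subscores, IST}) and
emotional ({HAD-A, HAD-D}), the recipe of the highest-t maximum among the
domain's scores; domains with no significant cluster are emitted as zero
columns flagged absent.

## The synthetic generator

The generator defines the study conditions everything else is tested
under:

* **Cohort.** 237 patients (187 train / 50 validation), age 65.4 ± 13.5
  years, 13 outcome scores drawn independently from truncated normals
  confined to each score's valid range. Parent parameters are
  moment-matched (least squares on the truncated mean/SD via `truncnorm`)
  so the simulated marginal reproduces the configured mean/SD — e.g. MoCA
  24.13 ± 4.93 on [0, 30] is matched exactly. For strongly ceilinged
  marginals no truncated normal attains the published moments (FM total
  224.93 ± 30.43 on [0, 242] would need (max − mean)/SD ≈ 0.56, below the
  family's floor of ≈ 1); the closest member is used, and this
  approximation is a documented limitation. FM motor and the MoCA subscores
  have no published marginals; field-realistic one-year defaults
  (mild residual impairment, ceiling-leaning subscores) are fixed in
  `default_score_params()`. Scores are simulated independently (no
  cross-score covariance is published); the MoCA total is simulated
  directly rather than as the sum of its subscores.
* **Split.** Pseudorandomization is best-of-K random splits (K = 1000)
  minimizing the maximum absolute standardized mean difference over the six
  main scores, stopping early at tolerance 0.1; if unreachable, the best
  split is returned with a warning.
* **Submissions.** 24 submissions from 15 teams (every team at least one).
  Feature combinations sample 0–8 inputs and 1–5 methods uniformly,
  matching the observed ranges in this kind of benchmark. Planted
  per-domain recipes sample 2–5 inputs and 1–3 methods, mirroring the size
  range of reported optimal combinations. Accuracy follows
  `r(match) = r_base + (r_max − r_base)·match^e` with defaults
  `r_base = 0.2`, `r_max = 0.8`, `e = 1` — the simplest monotone family
  with closed-form targets (match = 1 implies R² = 0.64 in expectation).
  Predictions are `r·z(truth) + sqrt(1 − r²)·noise`, rescaled to the
  truth's moments and clipped to the score range.

What the generator does **not** emulate: real imaging (feature bits are
declared, never computed from images), cross-score correlations, skewed or
multimodal score distributions, team-level correlation between submissions,
and any systematic bias in predictions (miscalibration, regression to the
mean). Tests passing on this generator therefore demonstrate the pipeline's
internal correctness and calibration, not clinical validity on real
cohorts.

## Known limitations

* **Recipe recovery is bounded by the submission cloud.** With 24 random
  feature combinations, the minimum Hamming distance from any submission to
  a planted recipe is typically ≥ 4, and because the inverse transform is
  anchored to observed submissions (a locality that the round-trip property
  requires), recipes read at t-maxima inherit that floor. In the recovery
  simulation the aggregated recipes land ~5–6 bits from the planted truth
  on average, and exact-to-within-2-bits recovery is rare (~2% of runs, as
  recomputed by `scripts/acceptance.R`). Recovering recipes precisely would
  require either many more submissions (denser coverage of the 2^17 design
  space) or submissions concentrated near the optimum.
* **Detection power at n = 24 is low.** Max-statistic FWE correction over
  3600 cells with 24 exchangeable units is stringent; many simulated runs
  yield no significant cluster for a given score, in which case that
  domain's recipe is flagged absent rather than guessed.
* The t-map emulates the *statistical design* of nonparametric
  neuroimaging inference (permutation null, max-t FWE); equivalence with
  any specific external implementation (variance smoothing, TFCE,
  cluster-extent options) is not claimed.
* UMAP hyperparameters (metric, neighbors, min-dist, seed) materially
  change the layout, so specific grid coordinates of maxima are not
  comparable across configurations — only the recipes and their
  domain-level aggregation are.

## Problem sizes used in the test suite

The suite exercises the pipeline at the study scale it emulates: 24
submissions, 13 scores, 60×60 grid. Simulation-heavy properties use sizes
chosen to make their Monte-Carlo error small relative to the asserted
margins: 10 000 patients for marginal moments, 1000–5000 validation
patients for the accuracy law, 200 repetitions × 1000 permutations for
FWE calibration, 20 end-to-end runs for recovery, 10 seeds for round-trip
fidelity.
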
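---
title: "Methods: graph-topology connectome features and two-stage classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-topology connectome features and two-stage classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`topoconn` implements a complete individual-level classification analysis for
resting-state functional connectomes. The chain is:

1. **ROI time series** (timepoints x regions) per subject, here produced by a
   seeded synthetic-cohort generator;
2. **temporal preprocessing**: initial-volume discard, linear detrend,
   zero-phase band-pass, confound regression, head-motion screening;
3. **partial-correlation connectome**: the conditional dependence of every
   region pair given all other regions, from a (shrinkage-regularized)
   precision matrix;
4. **binary networks over a sparsity grid** (fixed edge density per
   threshold) and **graph-topology metrics** at every threshold, normalized
   against degree-preserving random graphs where required;
5. **threshold-integrated features**: the area under each metric's curve
   across the grid, giving a 7 + 3N-dimensional vector per subject (277 for a
   90-region atlas);
6. **two-stage classifier**: stacked-autoencoder (SAE) dimensionality
   reduction followed by a linear SVM, evaluated with stratified 10-fold
   cross-validation, nested hyperparameter search, and a label-permutation
   test;
7. **feature attribution**: backward propagation of absolute weight
   contributions from the deepest hidden layer to the raw features.

The package is written so that every stage is independently callable and
testable; `run_pipeline()` chains them.

## The synthetic cohort generator

No subject-level imaging data ship with the package; the generator stands in
for a two-group resting-state study and defines the study conditions used by
the test suite:

* 33 subjects in group A (patients) and 53 in group B (controls), 90
  regions, 200 volumes at TR = 2 s, of which the first 10 are discarded
  downstream — matching a typical single-site pediatric cohort.
* Each group's signal is i.i.d. multivariate normal with covariance equal to
  the inverse of a group precision matrix, so the planted
  conditional-dependence structure is exactly the partial-correlation
  structure of the data. Rows are temporally white: hemodynamic
  autocorrelation is deliberately not modelled, so the band-pass stage is
  exercised on white noise and passing tests say nothing about coloured
  noise. There is no session, site, or motion-artifact structure either;
  passing tests demonstrate algorithmic correctness, not robustness to real
  scanner confounds.
* The shared support is a Watts-Strogatz graph (ring lattice, mean degree
  10, rewiring probability 0.1) with edge weights of random sign and
  magnitude 0.15-0.4, made positive definite by diagonal dominance
  (diagonal = absolute row sum + 0.5). This support produces estimated
  networks whose small-world index exceeds 1 across the sparsity grid.

### How the group effect is planted

The group difference must survive single-subject estimation noise: with
T = 190 retained volumes and N = 90 regions, the Ledoit-Wolf shrinkage
intensity is around 0.8 and the per-edge noise floor of the estimated
partial correlations is roughly 0.07. A diagonally-dominant precision caps
partial correlations near 1/degree (about 0.09 at mean degree 10), so any
magnitude-only rescaling of precision entries moves edges *within* the noise
floor and stays near chance downstream; such designs were evaluated and
rejected before adopting the current one.

The adopted effect converts the designated regions into **connector hubs**,
which is also the kind of reorganization the nodal metrics are built to
detect. For group B, with effect size `e`:

* the effect regions' lattice couplings are weakened by `1/(1 + e)`;
* each effect region gains star couplings at partial correlation
  `0.16 * e/(e + 0.25)` (alternating sign) to 10 deterministically spaced,
  distant satellite regions — a partial-correlation star is positive
  definite whenever the squared couplings sum below 1, so these strengths
  keep a comfortable margin for every `e` (the construction is additionally
  asserted positive definite at build time);
* the effect regions are mutually coupled at partial correlation
  `0.12 * e/(e + 0.25)`.

All changes are confined to the rows and columns of the effect regions, and
`e = 0` leaves the groups identical. The hub couplings sit 2-4 noise
standard deviations above the estimation floor, so the effect regions'
degree, betweenness, and nodal efficiency shift reliably per subject. The
test suite exercises both ends of the response: at the default
`effect_size = 1.5` the cross-validated pipeline exceeds 0.8 balanced
accuracy with a significant permutation test, and at `effect_size = 0`
repeated cohorts stay in the chance band with well-calibrated p-values.

## Preprocessing decisions

* **Motion screening.** The exclusion rule reads the absolute realignment
  parameters: a subject is excluded when any frame exceeds 1.0 mm of
  translation in any axis or 1.0 degree of rotation about any axis, with
  strict inequality at the limit. Framewise displacement is computed
  separately in the Power formulation — absolute frame-to-frame parameter
  change, rotations converted to arc length on a 50 mm sphere — and
  reported, not used for exclusion.
* **Filtering.** A 4th-order Butterworth band-pass (default 0.01-0.08 Hz)
  is applied forward and backward for zero phase, after per-region linear
  detrending. Band edges must lie strictly inside (0, Nyquist).
* **Confound regression** is ordinary least squares against an intercept
  plus caller-supplied columns; at ROI level the global signal is the row
  mean of all regions (`global_signal()`), and white-matter/CSF surrogates,
  if desired, are the caller's responsibility. Rank-deficient confound
  matrices fall back to the minimum-norm solution with a warning.
* **Order**: discard, then detrend + band-pass, then confound regression.
* For the synthetic cohort the pipeline default applies only the
  initial-volume discard: the generator produces trend-free, white,
  confound-free signal, and band-passing white data would only discard
  degrees of freedom. The filtering and regression stages are exercised by
  their own tests.

## Connectome decisions

* **Shrinkage.** With T barely exceeding N the sample covariance is
  near-singular. The default policy estimates the Ledoit-Wolf optimal
  intensity towards a scaled identity from the standardized data;
  `"none"` (plain inversion) is available for long-T analyses and errors
  when the covariance is not stably invertible (condition number guard at
  1e12). The intensity used is recorded on the result.
* **Sparsity thresholding** keeps the top `round(s * N(N-1)/2)` entries by
  absolute partial correlation — fixed edge *density*, so subjects are
  compared at equal cost. Rounding is half-away-from-zero and ties at the
  cut break by (row, column) index, making feature values bit-reproducible.
* **Grid.** Inclusive endpoints: 0.05 to 0.40 in steps of 0.01 = 36
  thresholds. Both endpoints and step are configurable.

## Graph metrics

Nodal clustering is `2 * triangles / (k(k-1))` with 0 for degree < 2; the
characteristic path length is the **harmonic mean** distance (the inverse of
global efficiency), which stays finite on disconnected graphs since
disconnected pairs contribute zero inverse distance; the identity
`Lp * Eglob = 1` is asserted in the test suite on every computed graph.
Local efficiency averages the global efficiency of each node's neighborhood
subgraph, with shortest paths confined to the subgraph (0 for degree < 2);
it is computed in-package by a dense matrix-power BFS because igraph's
`local_efficiency()` measures a different quantity (paths through the
surrounding graph). Betweenness is unnormalized Brandes betweenness
(endpoints excluded) — features are standardized downstream, so
normalization is immaterial. Other standard algorithms are delegated to
igraph; the test suite verifies every metric against hand-written
brute-force oracles (explicit BFS, exhaustive shortest-path enumeration) on
every connected graph with at most 7 nodes.

Normalized clustering (gamma), normalized path length (lambda), and
small-worldness (sigma = gamma/lambda) divide by the mean over an ensemble
of degree-preserving Maslov-Sneppen rewired graphs (10 x |edges| rewiring
trials per null). The package default is 100 nulls per threshold; the test
suite runs cohort-scale computations at 10 nulls per threshold, which
changes the null means by a few percent but leaves group contrasts intact —
the problem sizes used by each test are stated in the test itself. Graphs
admitting no swap (e.g. stars) return unchanged copies with a warning.
Metric curves integrate to scalars by the trapezoidal rule over the grid; a
rectangle rule would differ by a constant factor on smooth curves and
nothing downstream depends on the convention.

## Feature vector

Order is fixed: 7 global features (Cp, Lp, gamma, lambda, sigma, Eloc,
Eglob), then degree, betweenness, and efficiency blocks, each in atlas
region order — 277 features for the 90-region AAL atlas. Sigma is included
as the seventh global metric: it is computed per threshold alongside the
six others and 7 + 3 x 90 = 277 confirms seven global slots. The
`feature_table()` constructor refuses any name-order mismatch between
subjects rather than silently realigning columns.

## Two-stage classifier

* **Architecture.** Encoder 277 -> 128 -> 64 -> 32 -> 10 with sigmoid
  activations; greedy layer-wise autoencoder pretraining (linear decoders,
  MSE loss), then end-to-end fine-tuning with an appended 2-unit softmax
  label layer and cross-entropy loss. Training is full-batch Adam. The
  implementation is dense base-R linear algebra: at this scale (tens of
  subjects, hundreds of features) each fold trains in well under a second
  and runs are exactly reproducible from the seed.
* **Defaults**: 30 pretraining epochs per autoencoder, 100 fine-tuning
  epochs, learning rate 1e-3. All are explicit `sae_hyper()` fields
  recorded in results, not hidden constants.
* **Standardization** uses training-fold statistics only (z-score;
  non-finite features imputed with the training-fold median). The leakage
  contract — no held-out subject influences any training statistic — is
  enforced structurally (each fold recomputes everything from its training
  partition, including SAE weights) and audited by a test that corrupts the
  held-out fold and verifies bit-identical training statistics.
* **SVM stage**: linear SVM on the 10-dimensional codes; soft-margin cost C
  selected from {1e-3 ... 1e4} by stratified 5-fold inner cross-validation
  maximizing mean balanced accuracy, ties resolved to the smallest C
  (strongest regularization); refit on the full training fold.
* **Evaluation**: stratified 10-fold outer cross-validation; per-fold
  sensitivity (group A = patients = positive class), specificity, and
  balanced accuracy, aggregated as means across folds.
* **Permutation test**: the entire cross-validated pipeline is re-run under
  permuted labels (the pipeline seed held fixed, permutation draws seeded
  separately); p = count(permuted >= observed)/n_perm, ties counting
  against significance, reported as "< 1/n_perm" when the count is zero.
  Default 1000 permutations, configurable down for desk-scale runs.

## Attribution

From the fine-tuned interpretation model (one SAE trained on the full,
standardized cohort — distinct from the cross-validation models, and
trained longer by default, `sae_hyper(100, 500, 3e-3)`, because the
attribution reads trained weight magnitudes, which barely move from their
random initialization under short training), the
deepest hidden layer is scored by the column sums of the absolute outgoing
weights; the minimal node set whose contributions strictly exceed 50% is
retained; earlier layers are scored against the retained set of their
downstream layer; at the input layer all raw features are scored (no cut)
and normalized to sum to one. Squared-weight magnitudes are available as a
configuration toggle. Contributions are reported as a ranked top-10 table
with metric class and atlas region names. The procedure is scale-invariant
(rescaling any weight matrix by a positive constant leaves the ranking
unchanged) and permutation-equivariant in the input features; both are
asserted in tests.

## Numerical and degenerate-input conventions

* Constant time-series columns, empty sparsity grids, zero-edge
  binarization requests, single-class labels, and manifest schema
  violations are hard errors naming the offending field.
* Graphs with no finite-distance pair return `Inf` path length; non-finite
  metric values propagate through AUC as `Inf` and are imputed at the
  classifier stage with training-fold medians.
* All randomness flows through explicit seed arguments; functions save and
  restore the caller's RNG state, and derived per-subject/per-fold/
  per-threshold seeds stay below 2^31.

## Problem sizes used by the automated checks

The cohort-scale checks run at the study conditions (33 + 53 subjects, 90
regions, 190 retained volumes) with 10 rewired nulls per threshold, a
99-permutation significance test, and SAE epochs reduced to keep a full run
in minutes on one core; the null-calibration checks run 20 reduced cohorts
(12 + 12 subjects, 24 regions) with 19-permutation tests. These sizes are
choices recorded here and in the tests; the package defaults remain the
study-scale values given above.

## Known limitations

* The generator's Gaussian, temporally-white signal model cannot probe
  robustness to autocorrelation, non-stationarity, or motion artifacts.
* Binary undirected networks only; no weighted or directed variants, no
  modularity/rich-club analyses.
* The SAE is a compact dense implementation; it is not intended for
  voxel-scale inputs.
* Attribution reflects the trained interpretation model; contribution
  values are seed-dependent in small cohorts even when the top regions are
  stable.
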
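# topoconn

Individual-level classification of subjects from the graph topology of their
resting-state functional connectomes.

Case-control resting-state fMRI studies often find group differences in
network organization, but clinical utility requires calling the *individual*
subject. `topoconn` implements a complete, reproducible pipeline for that
task: from per-subject ROI time series to a partial-correlation connectome,
to threshold-integrated graph-topology features, to a two-stage deep
classifier with honest cross-validation and permutation-based significance,
and finally to a report of which (metric, brain region) features drove the
decision. A seeded synthetic-cohort generator with a planted group effect
makes every stage testable end to end without access to clinical data.

## The method

For each subject with ROI time series `X` (timepoints x N regions):

1. **Connectome.** The N x N partial-correlation matrix
   `p_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj)`, where `Theta` is the
   precision matrix of the column-standardized data, estimated with
   Ledoit-Wolf shrinkage towards a scaled identity (needed when timepoints
   barely exceed regions).
2. **Binary networks over a sparsity grid.** At each sparsity `S` in
   0.05-0.40 (step 0.01), keep the top `round(S * N(N-1)/2)` edges by
   `|p_ij|`, so all subjects are compared at equal edge density.
3. **Graph metrics per threshold.** Global: clustering coefficient `Cp`,
   harmonic-mean characteristic path length `Lp = 1/Eglob`, normalized
   clustering `gamma`, normalized path length `lambda`, small-worldness
   `sigma = gamma/lambda` (normalization against degree-preserving
   Maslov-Sneppen rewired graphs), local and global efficiency. Nodal:
   degree, betweenness centrality, nodal efficiency.
4. **Features.** Each metric's curve over the grid is integrated
   (trapezoidal AUC) into one scalar: 7 global + 3N nodal features = 277
   for a 90-region atlas.
5. **Classifier.** A stacked autoencoder (277 -> 128 -> 64 -> 32 -> 10,
   greedy unsupervised pretraining, then supervised fine-tuning with a
   2-unit label layer) reduces the features; a linear SVM on the
   10-dimensional codes classifies. Evaluation is stratified 10-fold
   cross-validation with a nested 5-fold search for the SVM cost
   `C in {1e-3 ... 1e4}`; performance is reported as balanced accuracy
   `(sensitivity + specificity)/2`, and significance by re-running the whole
   pipeline under label permutations.
6. **Attribution.** From a fine-tuned interpretation model, contributions
   propagate backward through the weight matrices (keeping, per layer, the
   nodes carrying > 50% of the contribution) down to the raw features; the
   top-10 (metric, region) pairs are reported.

See `vignettes/topoconn-methods.Rmd` for the design decisions, parameter
semantics, and the synthetic generator's planted-effect model.

## Worked example

A reduced synthetic study — 10 patients (group A) vs 12 controls (group B),
30 regions, with the planted hub effect in regions 1-5:

```r
library(topoconn)

cfg <- cohort_config(n_group_a = 10, n_group_b = 12, n_regions = 30,
                     n_timepoints = 120, effect_size = 1.5, seed = 42)
res <- run_pipeline(cfg,
                    grid = sparsity_grid(0.08, 0.32, 0.04),
                    null_m = 5, k_outer = 5, k_inner = 3,
                    layer_sizes = c(32L, 16L, 8L),
                    hyper = sae_hyper(15L, 40L),
                    n_perm = 49, seed = 42)
print(res$cv)
print(res$perm)
head(format_report(res$attribution), 5)
```

which prints:

```
<cv_result> 5 folds | balanced accuracy 0.683 +/- 0.199 | sensitivity 0.600 | specificity 0.767
<permutation_result> observed 0.683 | null mean 0.532 | p 0.04081633 (n_perm = 49)
  topological_property brain_region contribution
1    Nodal betweenness         R013       0.0232
2     Nodal efficiency         R003       0.0203
3         Nodal degree         R003       0.0196
4     Nodal efficiency         R013       0.0194
5    Nodal betweenness         R004       0.0182
```

Reading the output: the classifier separates the groups well above the
permutation null (balanced accuracy 0.683 vs null mean 0.532, p = 0.041 at
49 permutations), and the attribution report points at nodal metrics of
regions 3 and 4 — inside the planted effect set — plus region 13, one of
the satellite regions the planted hubs connect to. At the full study scale
(33 + 53 subjects, 90 regions) the test suite verifies that the same
pipeline exceeds 0.8 balanced accuracy with permutation p <= 0.02 and
places at least 3 of the 5 planted regions in the top-10 report in a
majority of seeded runs.

Real data enter through the same surfaces: `read_timeseries_tsv()` /
`validate_manifest()` for per-subject TSV time series and a cohort manifest
CSV, `read_motion_txt()` for SPM-style `rp_*.txt` motion parameters (with
`framewise_displacement()` and the 1 mm / 1 degree `motion_exclusion()`
rule), then the same `partial_correlation()` ->
`compute_metric_curves()` -> `assemble_features()` ->
`cross_validate_pipeline()` chain.

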
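# occupet

Simulation and kinetic analysis of dynamic PET receptor-occupancy
studies.

`occupet` is for researchers analysing (or planning) striatal
dopamine-release experiments with a reversible D2 tracer such as
¹¹C-raclopride: a subject is scanned at baseline and again after a
dopamine-elevating challenge, and the percent drop in non-displaceable
binding potential,

```
ΔBP = 100 · (BP_base − BP_post) / BP_base ,
```

indexes the evoked dopamine elevation. The package implements the whole
chain —

* **SRTM fitting.** Time-activity curves are fitted with the simplified
  reference tissue model
  `C_T(t) = R1·C_r(t) + (k2 − R1·k2a)·C_r(t) ⊗ exp(−k2a·t)`,
  `BP_ND = k2/k2a − 1`, by the basis-function method (log-spaced k2a
  grid, weighted linear subproblem per basis, 1-D refinement of the
  winning node), at ROI level (`fit_srtm()`) and voxel level
  (`fit_voxelwise()`, vectorised, with validity masking and a BP clamp).
* **Occupancy and reliability statistics.** `delta_bp()`,
  test–retest percent variability, ICC(1,1) of repeated baselines, exact
  Wilcoxon signed-rank (`wilcoxon_signed_rank()`).
* **Group contrasts.** Paired two-tailed t-tests per region
  (`paired_ttest()`, `build_table1()`), Bonferroni thresholds, Pearson
  covariate screens, and voxelwise paired contrasts rendered as
  (1 − p) significance maps displayed above 0.90
  (`voxelwise_contrast()`, `percent_significant_voxels()`).
* **A synthetic crossover cohort** (`simulate_cohort()`): 33-frame /
  120-min schedule (6 × 0.5, 3 × 1, 2 × 2, 22 × 5 min), cerebellum
  reference kinetics, condition-specific true ΔBP draws, frame-duration-
  and decay-dependent Gaussian noise, balanced session order, and
  null-correlated blood/behaviour covariates (plasma drug level,
  TNFα/IL-6/IL-8 curves, fatigue scores).
* **A digital striatum phantom** (`make_phantom()`,
  `render_dynamic_image()`, `extract_roi_tac()`) with bilateral
  ellipsoidal regions matched to template ROI volumes, for the voxel
  path.
* **A reproducible pipeline** (`run_pipeline()`): simulate or load TAC
  tables, fit, tabulate ΔBP and test–retest reports, optionally render
  the voxel path, and write TSV/JSON/NIfTI outputs with a checksum
  manifest. `scripts/run_pipeline.R` is a thin command-line wrapper.

Because raw data from such studies are generally unavailable, the
package is validated by parameter recovery: the simulator encodes known
truths and the analysis chain must return them.

## Worked example

Fit one noisy simulated TAC, then run a full 8-subject recovery:

```r
library(occupet)

sched <- make_frame_schedule(default_frame_spec())   # 33 frames, 120 min
ref   <- simulate_reference_tac()                    # cerebellum curve
y     <- simulate_target_tac(list(R1 = 1, k2 = 0.3, bp_nd = 2.5),
                             ref, sched, noise_scale = 0.1, seed = 1)
fit_srtm(y, ref, sched)
#> <srtm_fit: R1 = 1.0215, k2 = 0.2963 /min, k2a = 0.0844 /min, BP_ND = 2.5089>
```

The fit recovers the generating parameters (R1 = 1, k2 = 0.3/min,
BP_ND = 2.5) to within the noise: a single scan at this noise level
carries a BP uncertainty of well under 1%.

```r
recover_dbp_means(
  conditions = list("MP+LPS" = list(mean = 17.1, sd = 3.6),
                    "MP+PBO" = list(mean = 8.8, sd = 3.6)),
  region = "striatum", bp0 = 2.5, n_subjects = 8, seed = 0)
#>   condition true_mean estimated_mean n
#> 1    MP+LPS      17.1      16.625344 8
#> 2    MP+PBO       8.8       9.044096 8
```

Eight subjects are simulated with true ΔBP drawn from the two condition
cells (recentred so the sample means equal 17.1 and 8.8 exactly), all 32
scans are fitted, and the recovered condition means land within half a
percentage point of the truth — the residual is SRTM estimation noise,
not bias.

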
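# dceperf

Voxelwise quantification of exercise-induced calf-muscle perfusion from
dynamic contrast-enhanced (DCE) MRI, and a feed-forward classifier that
replaces the slow voxelwise deconvolution with near-instantaneous
inference.

## What it does

After a plantar-flexion exercise bout and a gadolinium bolus, a 2-D
slice is imaged at 1 s resolution; the first 40 frames carry the bolus
passage. Each muscle voxel's signal is converted to a tracer
concentration curve (TC) with the saturation-recovery relation
`S/PD = 1 − exp(−TD·(R10 + r1·C))`, and perfusion is estimated by
fitting the convolution of the arterial input function (AIF) with the
adiabatic tissue-homogeneity impulse retention function

```
IRF(t) = 0                                   t < t0
         F/6000                              t0 ≤ t < t0 + minTT
         (F/6000)·E·exp(−k(t − t0 − minTT))  t ≥ t0 + minTT
```

where `F` is perfusion (ml·min⁻¹·100g⁻¹), `t0` bolus arrival, `minTT`
minimal transit time, `E` extraction fraction and `k` excretion rate.
The package provides:

* **Fitting** — bounded Levenberg–Marquardt least squares per voxel,
  as a single-start "regular" fit (init `F` 350, `t0` 2 s, `minTT` 6 s,
  `E` 0.4, `k` 0.15 s⁻¹) or the 25-start "multigrid" fit over
  `F ∈ {100..300} × t0 ∈ {2..6}` that keeps the lowest-residual run and
  avoids the single start's local optima (`fit_voxel_regular()`,
  `fit_voxel_multigrid()`, `fit_map()`, `fit_study()`).
* **The network surrogate** — an 80-input (40 TC + 40 AIF points),
  7×70 ReLU, 40-class softmax classifier over perfusion values
  10–400 ml·min⁻¹·100g⁻¹, trained 20 epochs with Adam (lr 0.001,
  batch 32) on multigrid-fit labels; the decoded argmax gives
  grid-valued perfusion maps in well under a second per slice
  (`train_network()`, `predict_study()`, `predict_map()`).
* **A synthetic study generator** — gamma-variate AIFs whose first-pass
  area scales inversely with exercise-driven cardiac output, lognormal
  per-region perfusion fields, calibrated "diverse", "homogeneous" and
  "testing" cohort presets, Gaussian concentration noise, full NIfTI/CSV
  export (`generate_cohort()`, `export_study()`, `load_study()`).
* **Evaluation** — mean/SD/median, mean error, RMSE, MAE, Pearson R,
  paired t tests on absolute errors, error-versus-reference profiles in
  10-unit bins, perfusion histograms, and a one-call benchmark that
  reproduces the training-strategy comparison (`error_metrics()`,
  `compare_all()`, `binned_error_profile()`, `run_training_benchmark()`).

Results are tibbles; fitted objects have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures. A thin command-line tool
(`inst/cli/dceperf`) exposes `simulate`, `fit`, `train`, `predict`,
`evaluate` and `compare`.

## Worked example

```r
library(dceperf)
# simulate one held-out style study (40 frames at 1 s, SNR 20)
study <- generate_cohort(cohort_spec("testing"), seed = 7,
                         voxels_per_dataset = 400)[[1]]
study
#> <perf_study> testing_young_healthy_s01_4lb (testing): 400 voxels, 40 frames at 1 s, SNR 20

mg  <- fit_study(study, mode = "multigrid")
reg <- fit_study(study, mode = "regular")
glance(mg)
#> # A tibble: 1 × 7
#>   mode      n_voxels mean_F median_F  sd_F total_rss converged_fraction
#>   <chr>        <int>  <dbl>    <dbl> <dbl>     <dbl>              <dbl>
#> 1 multigrid      400   66.3     55.0  41.1      3.38                  1

report <- compare_all(
  tibble::tibble(truth = study$voxels$F,
                 multigrid = mg$voxels$F,
                 regular = reg$voxels$F),
  reference = "truth")
tidy(report)[, c("method", "mae", "rmse", "pearson_r")]
#> # A tibble: 3 × 4
#>   method      mae  rmse pearson_r
#>   <chr>     <dbl> <dbl>     <dbl>
#> 1 truth       0     0       1
#> 2 multigrid  10.5  20.0     0.889
#> 3 regular    11.3  16.1     0.915
```

The multigrid fit recovers this low-load dataset's perfusion with a mean
absolute error of ~10 ml·min⁻¹·100g⁻¹ at SNR 20; the advantage over the
single-start fit grows on high-load, high-perfusion datasets, where the
regular fit's errors concentrate (see the vignette and
`run_training_benchmark()` for the full comparison including the
networks trained on diverse vs homogeneous cohorts and on regular-fit
labels).

## Package layout

`R/` tidyverse-facing API over the compiled core in `src/` (kinetic
model, bounded LM multigrid fitter, MLP classifier); cohort presets in
`inst/extdata/presets/`; methods vignette in `vignettes/`; tests under
`tests/testthat/` including the end-to-end scientific acceptance suite.
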
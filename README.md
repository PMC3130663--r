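# mriresponse

Early prediction of tumor treatment response from longitudinal functional
MRI biomarkers, evaluated end to end on calibrated synthetic data.

## The problem

In a four-arm preclinical design — untreated control, single-dose
radiotherapy (RT), androgen deprivation (ADT), and ADT+RT — prostate
carcinoma xenografts are imaged before treatment and on days 1 and 9.
Two functional MRI biomarkers are derived per tumor:

- **ADC** (apparent diffusion coefficient, mm²/s): the mono-exponential
  decay rate of the diffusion-weighted signal, `S(b) = S₀·exp(−b·ADC)`,
  acquired at b = 0 and 100 s/mm² in six gradient directions. ADC rises
  as therapy reduces cellularity.
- **K^trans** (volume transfer constant, 1/s): from the Tofts model of
  dynamic contrast-enhanced MRI,
  `C_t(t) = K^trans ∫₀ᵗ C_p(τ)·e^{−k_ep(t−τ)} dτ`, `k_ep = K^trans/v_e`,
  with the biexponential vascular input function
  `C_p(t) = 3.57·e^{−0.025t} + 1.45·e^{−0.0074t}` mM. K^trans falls under
  anti-vascular treatment effects.

These biomarkers, together with tumor volume V and serum PSA — all
normalized to each animal's day-0 baseline — plus one-hot treatment-group
codes, feed a small back-propagation neural network (BPNN, one hidden
layer of six tanh units, scaled-conjugate-gradient training with
validation-based early stopping) that predicts the day-30 endpoint
`V30/V0`. Prediction quality is the Pearson correlation r between
predicted and measured response on held-out test animals, under repeated
stratified 50/25/25 splits. The scientific question: do ADC and K^trans
carry complementary information, i.e. does the all-inputs model beat
either single-modality model?

Because no raw data from such an experiment are public, the package
includes a calibrated synthetic cohort generator (group-mean day-30
volume changes of +940%, +60%, −40%, −64%; a shared per-animal latent
linking biomarker changes to outcome; outcome noise calibrated so the
generative oracle achieves r ≈ 0.90) and voxel-level DW/DCE simulators
with Rician/Gaussian noise, so every estimator is testable against known
ground truth. See the methods vignette
(`vignettes/response-prediction.Rmd`) for the full model.

## Worked example

```r
library(mriresponse)

cfg <- generator_config()           # the calibrated study conditions
cohort <- simulate_cohort(cfg, seed = 1)
print(cohort)
#> <mri_cohort> 32 animals in 4 groups (seed 1)
#>   mean V30/V0 - 1 per group:
#>     control: +8.778
#>     RT: +0.832
#>     ADT: -0.262
#>     ADT+RT: -0.624

report <- reproduce_study(generator_config(n_per_group = 32),
                          seed = 1, n_repeats = 15)
report$table
#>   input_set median_r iqr_lo iqr_hi median_p pooled_r  pooled_p
#> 1       adc    0.854  0.815  0.899 4.92e-10    0.818 8.49e-117
#> 2    ktrans    0.909  0.900  0.930 5.93e-13    0.873 4.91e-151
#> 3       all    0.920  0.900  0.946 9.22e-14    0.906 5.16e-181
```

The 32-animal cohort's group means scatter around the calibrated values
(+9.40, +0.60, −0.40, −0.64 as fractions); at 1000 animals per group they
converge to them. In the report table, each row is one input set:
`median_r` is the median over 15 resampled splits of the test-set Pearson
correlation between predicted and measured `V30/V0`, with its
interquartile range; `pooled_r` pools all test predictions. The
all-inputs model (last row) exceeds both single-modality models —
the complementary-information effect the pipeline is designed to detect.

Lower-level interfaces mirror the analysis stages: `simulate_dw_stack()`
/ `compute_adc_map()` / `roi_mean()` for diffusion,
`simulate_dce_series()` / `fit_tofts_voxel()` / `roi_mean_ktrans()` for
perfusion, `bpnn()` (with `predict`, `plot`, `summary`, `coef`,
`residuals` methods) for the network, `build_features()`,
`run_simulation()` and `apply_imaging()` for the pipeline.

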
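# spectromyo

Movement-segmented power-spectrum analysis of surface electromyography
(sEMG), built around a clinical question: can the spectral content of leg
sEMG recorded during a simple, non-fatiguing knee flexion–extension task
quantify the shift toward fast-glycolytic (type II) muscle fibers seen in
COPD? Higher type II content shifts the sEMG power spectral density toward
higher frequencies, so the package estimates, per movement half-cycle and
muscle (Rectus Femoris, Vastus Lateralis, Vastus Medialis, Biceps Femoris):

- **MNF**, the power-weighted mean frequency
  `MNF = Σ f_j P_j / Σ P_j`, and
- **MDF**, the median frequency satisfying
  `Σ_{j≤MDF} P_j = Σ_{j≥MDF} P_j = ½ Σ_j P_j`,

from Welch 512-point FFT PSDs of the high-passed raw sEMG, alongside the
integrated envelope area per movement. The most common spectral shapes are
characterized by PCA with varimax rotation, each profile quantified by its
Pearson *weighting coefficient* on each rotated component, and the
statistics layer provides pooled t-tests, mixed two-way ANOVA with partial
eta-squared, one-way repeated-measures ANOVA with Greenhouse–Geisser
correction, and Pearson regressions of MNF/MDF against spirometric disease
severity (FEV1, FEV1/FVC).

Because the original clinical recordings are not publicly deposited, the
package includes a seeded synthetic cohort generator whose spectral and
amplitude structure is analytically known (two-pole shaping spectrum,
frequency-calibrated so the injected COPD/control MNF ratio is exact),
so the entire chain is testable end to end. See
`vignettes/spectromyo-methods.Rmd` for the model and all design choices.

## Worked example

```r
library(spectromyo)

cfg <- pipeline_config(
  cohort = cohort_config(n_per_group = 10, seed = 1),  # 10 COPD + 10 control
  out_dir = "spectromyo-out")
res <- run_pipeline(cfg)

res$group_comparison[, c("muscle", "direction", "mnf_copd", "mnf_control",
                         "mnf_pct_diff", "mnf_p", "area_pct_diff", "area_p")]
```

```
  muscle direction mnf_copd mnf_control mnf_pct_diff     mnf_p area_pct_diff    area_p
1     RF extension    149.4       116.3        28.40 1.690e-09        -39.48 2.439e-10
2     RF   flexion    165.1       137.2        20.33 2.570e-08        -39.95 1.819e-09
3     VL extension    147.5       121.1        21.84 4.932e-08        -39.24 3.322e-07
4     VL   flexion    163.3       141.3        15.57 2.322e-06        -38.86 5.474e-06
5     VM extension    152.3       121.0        25.81 2.767e-08        -43.42 6.199e-14
6     VM   flexion    167.4       139.7        19.84 2.299e-07        -44.91 4.304e-13
7     BF extension    164.2       146.7        11.91 1.093e-05        -35.50 1.163e-07
8     BF   flexion    146.0       122.3        19.34 1.282e-07        -36.53 6.965e-09
```

The generator injected a +25% analytic MNF shift and a 0.6 amplitude ratio
for the COPD group; at n = 10 + 10 the pipeline recovers a +28% MNF
difference for RF extension (p ≈ 2e-9) and a ~39% lower sEMG area — the
synthetic analogue of the clinical finding the package is designed to
detect. `run_pipeline()` also writes `features.csv`, `areas.csv`,
`events.csv`, `segments.csv`, `pca_summary.csv`, `components.csv`,
`table3_like.csv` (mixed ANOVA), `table5_like.csv` (severity regressions)
and a `summary.json` echoing every flag in effect; reruns with the same
seed are byte-identical.

Lower-level entry points mirror the processing chain: `generate_cohort()`,
`filter_angle()` / `detect_events()` / `build_segments()`,
`highpass_emg()` / `rectify_debias()` / `envelope_emg()` / `segment_area()`,
`compute_psd()` / `mnf()` / `mdf()`, `build_profile_matrix()` /
`fit_pca_varimax()` / `weighting_coefficients()` /
`compare_group_weights()`, and the statistics functions
(`two_sample_t()`, `mixed_anova_2way()`, `rm_anova_1way_gg()`,
`severity_regression()`). A CLI wrapper is installed at
`inst/cli/spectromyo` (`spectromyo simulate|run|report`).

The package ships the published anthropometric and spirometry tables as
plain-text fixtures (`copd_anthropometrics()`, `copd_clinical()`); the
pooled t-tests on the printed age and height columns reproduce the
published p-values (0.801 and 0.851) exactly, which the acceptance tests
assert.

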
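---
title: "Methods: movement-segmented sEMG spectral analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement-segmented sEMG spectral analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chronic obstructive pulmonary disease (COPD) remodels peripheral skeletal
muscle toward fast-glycolytic (type II) fibers. Because type II motor units
conduct action potentials faster, their surface EMG content sits at higher
frequencies: a shift of the sEMG power spectrum toward high frequencies is
an established non-invasive correlate of fiber-type composition. This
package implements the full analysis chain for quantifying that shift
during a *non-fatiguing* task — seated knee flexion–extension cycles — in
which amplitude stays stable over cycles so that the spectral shift is not
confounded by fatigue:

1. kinematic event detection on a goniometer trace and segmentation into
   direction-tagged half-cycles;
2. time-domain sEMG processing (high-pass, rectification, background
   subtraction, linear envelope, integrated area per movement);
3. per-segment power spectral densities with mean frequency (MNF) and
   median frequency (MDF);
4. PCA with varimax rotation of the pooled spectral profiles, plus Pearson
   "weighting coefficients" of each profile on each component;
5. the group statistics layer (Student's t, mixed two-way ANOVA with
   partial eta-squared, one-way repeated-measures ANOVA with
   Greenhouse–Geisser correction, and Pearson regressions of MNF/MDF
   against spirometric severity, FEV1 and FEV1/FVC).

Because the clinical recordings behind the original study are not public,
the package ships a first-class synthetic cohort generator with analytic
ground truth, so every stage can be validated quantitatively.

## Signal chain and its parameters

All filters are 2nd-order Butterworth applied forward and backward
("zero-lag"; the magnitude response is applied twice, phase cancels). The
filter core is implemented in the package (with an Rcpp inner loop,
scipy-compatible odd-reflection padding and steady-state initial
conditions) because no digital-filtering package is available in the
supported dependency set; it is tested against the closed-form magnitude
response of a twice-applied 2nd-order Butterworth.

| stage | filter | default | why |
|---|---|---|---|
| knee angle | low-pass | 5 Hz, 200 Hz sampling | standard kinematic smoothing |
| sEMG artifact removal | high-pass | 20 Hz, 1000 Hz sampling | electrode-movement artifacts |
| envelope | low-pass on rectified signal | 10 Hz | linear envelope for areas |

The high-pass *order* is not specified by the source methodology; we use
2nd order zero-phase to parallel the other filters (configurable).

Movement onset is the first time the absolute angular velocity (central
difference) exceeds 5% of its global peak for at least 50 ms — a standard
noise-robust kinematic onset rule; the threshold pair is configurable.
Peaks are alternating local extrema with prominence at least 10% of the
angular range (the task is "maximal range of motion", so true peaks
dominate any ripple). Extension segment k runs from the preceding flexion
peak (onset for k = 1) to extension peak k; flexion segment k from
extension peak k to flexion peak k. Only the first 9 cycles are analyzed:
the final cycle is routinely anticipated and irregular.

Background subtraction uses one global level per channel per recording —
the mean rectified amplitude over the 500 ms immediately preceding onset —
and clips negative values to zero so envelope and area stay non-negative
(the source is silent on both points). Areas are trapezoidal integrals of
the envelope over each segment.

## Spectral estimation

Spectra are computed on the **high-passed, unrectified** signal ("raw
sEMG"), never on the envelope. The stated FFT length is 512 points, but
movement segments have variable length (≈500–1000 samples at 1000 Hz); we
adopt Welch averaging with 512-sample Hann windows at 50% overlap so all
samples contribute, and fall back to a single zero-padded 512-point window
(flagged) for segments shorter than 512 samples. Scaling satisfies
Parseval exactly: the sum of `P * df` over all bins equals the
window-corrected mean square of the segment (the Hann-weighted mean square,
averaged over windows); the test suite verifies this to better than 1% for
every PSD it produces. The analysis band is [20, 500] Hz: the lower edge
matches the 20 Hz hardware high-pass, the upper edge is Nyquist.

MNF is the power-weighted mean over band bins,
`sum(f_j P_j) / sum(P_j)`. MDF is the frequency at which cumulative power
reaches half the total. Since the raw definition only resolves a bin index
(bin width ≈ 1.95 Hz), the default interpolates linearly *within* the
crossing bin, treating bin j's power as spread over `f_j ± df/2`. This
convention keeps two identities exact: all power in one bin returns that
bin's frequency, and a mirror-symmetric spectrum returns its center. The
discrete-bin answer is available via `mdf(..., interpolate = FALSE)`.
Zero-power and sub-64-sample segments are skipped with a warning rather
than producing undefined features.

## PCA of spectral profiles

For each muscle × direction, all per-segment PSDs of both groups are pooled
into a profile matrix. By default rows are normalized to unit area —
amplitude differences are already captured by the sEMG area, so PCA should
characterize *shape* — and the PCA itself is computed on the column-centered
(covariance) matrix, preserving the spectral metric across bins. Both
choices are open in the source methodology and are exposed as switches.

Components with at least 10% of total variance are retained (at least 2, at
most 4 — a rule reverse-engineered from the 3–4 components typically
reported) and varimax-rotated. The rotation matrix is computed from the
eigenvalue-scaled loadings, which is the standard (SPSS-like) varimax
criterion, but is applied to the orthonormal component basis. This makes
the returned components exactly orthonormal and preserves the retained
variance sum exactly, at the cost of the rotation criterion being evaluated
on the scaled rather than the unit basis; variance proportions are
recomputed post-rotation and components re-ordered by explained variance,
each sign-flipped so its largest-magnitude element is positive.

Weighting coefficients are Pearson correlations between each original
(uncentered) profile row and each component, across frequency bins. Group
distributions of weighting coefficients are compared per component with a
two-sample Student's t-test on Fisher-z-transformed values — the source
does not name its test; z-transformation is variance-stabilizing for
correlations, and the test suite checks the resulting p against a
10,000-draw permutation oracle. Components are summarized by their centroid
frequency `sum(f * component^2)` (components are unit-norm), which is how
"high-frequency" versus "low-frequency" components are identified
programmatically.

## Statistics layer

- Parametric gates: Shapiro–Wilk per sample and Levene's test with
  center = mean (absolute deviations from the group mean, one-way ANOVA),
  passing when all p > 0.05.
- Group comparisons use the pooled-variance Student's t-test by default
  (the gate on Levene justifies pooling); Welch is behind a flag. Cycle
  values are averaged per participant × muscle × direction before any group
  test — groups are compared at n participants, not n × cycles.
- The mixed two-way ANOVA has group as between factor and frequency
  parameter (MNF vs MDF) as a two-level within factor, with each effect
  tested against its proper stratum and partial eta-squared
  `SS_effect / (SS_effect + SS_error)`. With the within factor collapsed it
  reduces exactly to the pooled t-test (F = t²), which the tests assert to
  1e-10.
- Cycle stability uses a one-way repeated-measures ANOVA over the 9 cycles
  with Greenhouse–Geisser correction; epsilon is estimated from the
  covariance of orthonormalized within-participant contrasts and applied to
  both degrees of freedom. Huynh–Feldt is not implemented. Note that the
  Greenhouse–Geisser estimator is biased downward in small samples: under
  exact compound symmetry with k = 9 levels its mean is ≈ 0.57 at n = 12
  and ≈ 0.78 at n = 30. The calibration test therefore uses n = 30, which
  checks the sphericity property rather than the estimator's known
  small-sample bias.
- Severity regressions report Pearson r and two-tailed p of participant
  mean MNF/MDF against FEV1 and FEV1/FVC per muscle × direction. No
  multiple-testing correction is applied by default, matching the original
  per-muscle local tests; Holm is available behind a flag.

## The synthetic cohort: what it emulates and what it does not

The source study measures spectra but has no generative model, so the
generator adopts the classic two-pole EMG shaping spectrum

G(f) = g² f_h⁴ f² / ((f² + f_l²)(f² + f_h²)²),

which is unimodal, zero at DC, and right-skewed with a wide high-frequency
tail — the qualitative profile shape described for patient spectra. It is
analytically tractable: band-limited MNF and MDF of G are computed by
quadrature (`analytic_mnf_mdf()`) and serve as ground truth.

Each channel is `envelope(t) · shaped_noise(t) + background`:

- *Shaped noise* is Gaussian noise colored in the frequency domain
  (multiply a white spectrum by √G, inverse transform, normalize to unit
  variance) — the target PSD is exact by construction, with no
  filter-design ambiguity.
- *Envelopes* are raised-cosine bursts spanning each active half-cycle with
  a 10% rise/fall fraction; extensors (RF, VL, VM) burst during extension,
  BF during flexion; the antagonist phase gets 5% of the agonist gain
  (small co-activation) so antagonist segments remain analyzable.
- *Background* is white Gaussian with σ = 2% of burst RMS.
- *Group effect*: COPD parameters are found by numerically scaling
  (f_l, f_h) jointly until the band-limited analytic MNF ratio
  COPD/control equals `mnf_shift_factor` **exactly** (default 1.25, the
  largest reported extension-movement shift), and multiplying the gain by
  `amplitude_ratio` (default 0.6, emulating the reported sEMG-area
  reduction). An unattainable ratio (pushed past Nyquist) is a parameter
  error.
- *Between-subject variance*: gain and f_h are jittered log-normally
  (σ_log = 0.1) per participant, giving the statistics layer realistic
  subject-level spread (~6–10% CV in MNF).
- *Kinematics*: 1 s quiet baseline, then 10 sinusoidal cycles of 2 s
  (cadence is not reported by the source; 0.5 Hz is a comfortable seated
  leg-swing and is a free parameter), 80° peak-to-peak, extension first.
  Goniometer noise defaults to zero: it is negligible after the 5 Hz
  zero-phase filter, and a zero default keeps the generator's ±1-sample
  peak-time guarantee exact rather than probabilistic.

The generator does **not** simulate motor-unit spike trains or MUAPs,
force, fatigue, electrode geometry, or any coupling between spectral shift
and the shipped clinical records. Consequently a green synthetic test
establishes that the *pipeline* recovers injected spectral and amplitude
effects at clinical sample sizes — it says nothing about physiology. The
severity-regression layer is exercised by pairing synthetic patients with
the shipped spirometry fixture in id order; this synthetic pairing checks
table plumbing, not a clinical association (synthetic features are
independent of FEV1 by construction, which is exactly what the calibration
test asserts).

## Numerical choices and degenerate inputs

- Filtering requires > 12 samples (odd-reflection pad of 3× the filter
  length); shorter traces are input errors.
- Detection errors: flat traces, never-sustained velocity, or
  non-alternating extrema after prominence pruning.
- `rectify_debias()` needs 500 ms of pre-onset data; onset earlier than
  that is an input error.
- PSD segments shorter than 64 samples are skipped with a warning; a
  participant with zero valid segments is an error.
- Degenerate profile matrices (rank < 2) are model errors; zero-variance
  profile rows get NA weighting coefficients with a warning.
- Constant samples make Shapiro/Levene undefined; they are flagged rather
  than raised.
- All randomness flows from one master seed; per-participant streams are
  derived by a deterministic polynomial hash of (seed, participant id), so
  cohorts are bit-reproducible and participants are independent of cohort
  composition.

## Known limitations

- The Welch/512 mapping of variable-length segments onto the stated
  512-point FFT is one defensible reading of an under-specified method;
  `psd_mode = "single512"` provides the stricter fixed-window reading.
- The 20 Hz zero-phase high-pass attenuates real signal content up to
  ≈40 Hz; empirical pipeline MNF is therefore biased up by ≈2–3% relative
  to the generating spectrum's analytic MNF. Group *ratios* are unaffected
  (the bias cancels), and the generator-fidelity test compares unfiltered
  segments against the analytic truth.
- Between-group tests assume participant-level means are exchangeable;
  cycle-level correlation structure is only used by the repeated-measures
  layer.
- Huynh–Feldt epsilon, promax/ICA variants, and score-based patient
  classification are out of scope.
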
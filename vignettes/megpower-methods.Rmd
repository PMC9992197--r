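---
title: "megpower: methods and design notes"
author: "megpower maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{megpower: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

megpower implements a resting-state MEG spectral-power analysis in
source space, of the kind used to compare patient groups in pediatric
focal epilepsy, and pairs it with a synthetic cohort generator so that
every stage can be validated against a known ground truth. The chain is:

1. **Simulate** (or load) multichannel magnetometer recordings plus an
   empty-room noise recording and a clinical covariate table for three
   groups: cognitively impaired patients (CI, full-scale IQ < 90),
   cognitively non-impaired patients (CNI, FSIQ > 90), and healthy
   controls (HC).
2. **Preprocess**: zero-phase notch at the 50 Hz powerline frequency and
   its harmonics; selection of one artifact-free 30 s analysis segment;
   noise covariance from the empty room with diagonal shrinkage.
3. **Forward model**: the Sarvas closed-form magnetic field of a current
   dipole in a homogeneous conducting sphere, with fixed dipole
   orientations along the source normals.
4. **Inverse**: a depth-weighted minimum-norm estimate (MNE) with
   regularization `lambda2 = 0.33`, the reciprocal of the assumed
   sensor-level SNR (about 3).
5. **Spectra**: Welch power spectral density (5 s Hann windows, 50%
   overlap) per source vertex, averaged within each of 26 bilateral
   triple-network ROIs, integrated over eight analysis bands, and
   normalized to *relative* power (each band's share of the summed power
   of the analysed bands; values in [0, 1], summing to 1).
6. **Statistics**: Shapiro-Wilk normality gate, Kruskal-Wallis omnibus
   test per (ROI, band), Mann-Whitney pairwise post hocs with Bonferroni
   adjustment, Benjamini-Hochberg FDR over the reporting family, and
   Pearson/Spearman correlations between clinical covariates and
   relative power.

The 26 ROIs are 13 Desikan-Killiany-named bilateral areas covering the
default-mode, central-executive and salience ("triple") networks:
CAC, CMF, IPL, IC, MT, PaH, PCC, PCu, RACC, RMF, SF, ST, SM, each with
`.L`/`.R` hemisphere labels (`roiNames()` fixes the canonical order).

# The statistical model of the generator

Source activity at vertex $v$ belonging to ROI $r$ is

$$ s_v(t) \;=\; b_v(t) \;+\; \sum_{\beta} m_{g}(r, \beta)\, A_\beta\,
   o_{r,\beta}(t), $$

where $b_v$ is 1/f background (a low-rank spatial mixture of shared
Gaussian components with power spectral density $\propto f^{-1}$),
$o_{r,\beta}$ is a band-limited Gaussian oscillator shared coherently by
the ROI's vertices, $A_\beta$ a per-band base amplitude, and
$m_g(r,\beta)$ the group's effect multiplier (1 unless the effect map
says otherwise). Oscillators are synthesized in the frequency domain
with a Gaussian bump envelope truncated to the band, so band spectra are
exactly disjoint and the *expected* time-domain variance scales exactly
with the squared multiplier — the controlled truth the validation
experiments recover. Sensor data are

$$ x(t) = G\,s(t) + \varepsilon(t) + \ell(t), $$

with $G$ the Sarvas lead field, $\varepsilon$ white sensor noise, and
$\ell$ a common 50 Hz sinusoid with per-channel gains (the powerline
component the notch is later asked to remove).

The default effect map encodes the qualitative group differences the
cohort emulates: delta-band amplitude raised and alpha lowered in both
patient groups across all 26 ROIs, theta raised in CNI, and a high-band
(beta and above) decrease confined to the insular, superior/middle
temporal and parahippocampal areas. Clinical covariates are drawn
independently per subject from Gaussians matching the published group
means and SDs, truncated where the group definition demands it
(CI: FSIQ < 90; CNI: FSIQ > 90). Because those published statistics
describe the *already truncated* groups, the generator moment-matches
the parent distribution so that the truncated draws reproduce the
published mean and SD rather than biased versions of them.

## What the generator does and does not emulate

It emulates: the recording scale (a 275-channel whole-head magnetometer
helmet at 6,000 Hz for 2 minutes, reachable via design fields), powerline
contamination, instrument noise measurable in an empty room, 1/f
background with band-limited rhythms, bilateral ROI structure with
depth-varying sources, and group effects of controllable size and
direction.

It does not emulate: realistic folded cortical geometry (sources sit on
a thick spherical shell with deterministically tilted orientations —
purely radial dipoles would be externally silent in a spherical
conductor), epileptic spike waveforms (the emulated protocol analyses
spike-free segments), eye-blink/cardiac artifacts, head movement, or
any covariance structure between clinical covariates. Passing tests
therefore demonstrate the *correctness and calibration of the analysis
chain*, not performance claims about real patient data.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `lambda2` | 0.33 | – | Tikhonov weight of the MNE; reciprocal of assumed SNR (~3) under the trace-normalized prior |
| depth exponent | 0.5 | – | conventional distributed-MNE depth weighting $w_s = (g_s^\top g_s)^{-0.5}$ |
| depth limit | 10 | – | clips the prior's dynamic range to limit$^2$ |
| covariance shrinkage | 0.1 | – | guarantees an invertible whitener at desk scale |
| notch bandwidth | 2 | Hz | second-order Butterworth band-stop per harmonic, applied forward-backward |
| segment length | 30 | s | analysis window; stability of resting spectra |
| artifact threshold | 5 (function) / 7 (pipeline) | robust SDs | see below |
| Welch window / overlap | 5 s / 50% | – | 0.2 Hz bins; 11 segments per 30 s |
| bands | delta 2–4 … fast ripple 250–500 | Hz | fixed scheme; both edges inclusive, a shared edge belongs to the lower band |
| `sourceAmplitude` | 1e-8 | A·m | dipole moment scale of a unit-multiplier oscillator |
| `sensorNoiseSd` | 1e-13 | T | 100 fT instrument noise |
| `lineAmplitude` | 5e-13 | T | clearly visible 50 Hz peak before the notch |

Band gaps (4–5, 7–8, 12–15, 29–30 Hz) belong to no band and never enter
the relative-power denominator; at sampling rates that cannot represent
a band (fast ripple needs > 1000 Hz) the band is dropped with a warning
and the denominator re-spans the remaining bands.

# Numerical and design choices

**Visual artifact vetting replaced by a rule.** The emulated protocol
rejects artifact segments by visual inspection. We replace this with the
first window whose per-channel peak amplitude stays below `thresholdK`
robust SDs (median absolute deviation, Gaussian-consistent). The
function default is 5; the pipeline passes 7 because, for Gaussian data
with 64 channels x 18,000 samples, a 5-SD peak test false-alarms on a
substantial fraction of perfectly clean windows (expected exceedances
per window ≈ 0.65) and even a 6-SD test false-alarms with probability
~2e-3 per window — enough to abort one subject in a thousand-subject
simulation campaign — whereas at 7 SDs the probability is ~3e-6. The
expected clean-data maximum is ~4.5 robust SDs and simulated artifact
bursts sit tens of SDs out, so the choice follows from extreme-value
arithmetic, not tuning.
When no window passes, the error is explicit; nothing is silently
truncated.

**ROI spectral reduction is power-first.** The PSD is computed per
vertex and then averaged over the ROI, so anti-phase vertices cannot
cancel. The mean-first alternative (PSD of the ROI-mean time series) is
available via `reduce = "mean-first"` for comparison. The production
path (`roiPsdKernel()`) applies the inverse kernel to the windowed
sensor spectra per frequency bin — algebraically identical to explicit
source reconstruction followed by per-vertex Welch (both are linear maps
commuting with the windowed Fourier transform), verified to 1e-9 in the
tests, and roughly an order of magnitude cheaper.

**Relative-power denominator.** The normalization divides by the summed
power of the *analysed bands only* (not the whole spectrum), so the
values are exact band shares that sum to 1. The alternative
whole-spectrum denominator would include the deliberate band gaps; both
readings exist in practice, and the band-share one is what makes rows
sum to unity.

**Single best-fit sphere.** With a synthetic spherical source space,
per-sensor overlapping spheres and the single least-squares sphere
coincide; the lead-field API accepts a per-sensor sphere list as the
extension hook for realistic geometry.

**Prior normalization.** The source prior is scaled so that
trace$(LRL^\top)/n_{\text{sensors}} = 1$ after whitening, which is what
makes `lambda2` interpretable as the reciprocal SNR. Other software
families use slightly different internal conventions; ours is declared,
not claimed identical.

**Statistics conventions.** Identical observations give H = 0, p = 1.
The exact permutation p (total n ≤ 10, or on request) counts
assignments with H at least as large as observed, by full enumeration.
Bonferroni is applied within a cell (×3 pairwise contrasts), BH-FDR
across the 26 ROIs of one band and one contrast — matching per-band
reporting; a global family is available by option. The 0.005 reporting
cut is applied to the raw p for omnibus rows and to the
Bonferroni-adjusted p for pairwise rows. Correlation p's are
FDR-corrected within (group, clinical variable, band) families.

**Chi-square vs exact permutation.** The chi-square reference for the
Kruskal-Wallis H is an approximation: at group sizes (4,4,4) its mean
absolute deviation from the enumerated permutation p is about 0.03
(about 0.05 at (3,3,3)). The test suite asserts this honest magnitude.

# Problem sizes used by the validation experiments

All validation runs use the desk-scale conditions: 64 sensors, 520
shell vertices, 600 Hz sampling (the fast-ripple band is dropped at
this rate, leaving 7 bands).

* **Null calibration**: 6 independent effect-free cohorts, 8 subjects
  per group, 60 s recordings — 1,092 (ROI, band) cells. Cells within a
  cohort share subjects and are correlated, so several cohorts are
  needed for the rejection rate to concentrate; the marginal
  Kruskal-Wallis rejection rate at (8,8,8) and nominal 0.05 is ~0.045.
* **Effect recovery**: 20 seeded studies, 24 subjects per group (CI and
  HC), 32 s recordings (one 30 s analysis window plus margin), with the
  delta-band oscillator amplitude doubled in bilateral PCC for CI.
  Each study runs the full chain and asks whether (PCC, delta) lands in
  the CI-HC FDR rejection set and whether the recovered direction is
  delta up / alpha down.
* **Monotonicity**: multipliers 1, 1.5, 2 with 20 subjects each on the
  same scale.
* **Biot-Savart oracle**: a tangential dipole at half the sphere radius;
  the volume-current quadrature uses a 40x48x64 interior grid plus
  sensor-centred ray quadrature for the singular part.

# Known limitations

* The spherical-shell geometry makes left/right ROI pairs exactly
  symmetric; real lateralization effects have no analogue here.
* Oscillators are coherent within an ROI and independent across ROIs;
  real cortical rhythms have long-range coherence that would change
  leakage behaviour.
* The exact permutation path enumerates all assignments and is only
  practical for total n around 12.
* A FIF/real-data adapter is an extension point: the documented
  recording container (`writeRecording()`) is the package's interchange
  format.
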
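---
title: "Methods: forward model, processing pipeline and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward model, processing pipeline and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`seatvitals` models the measurement chain of a seat-based cardiovascular
monitor: three synchronized channels — single-lead ECG (mV), summed
load-cell BCG force (N) and dual-wavelength PPG (arbitrary optical units)
— are processed into calibrated estimates of systolic/diastolic blood
pressure, SpO₂, stroke volume and cardiac output, and the estimates are
held to device-validation statistics. Since paired seat/gold-standard
recordings are not generally available, the package's forward generator
is a first-class component: it encodes configurable ground-truth vitals
into the waveforms so that the whole chain can be tested by parameter
recovery.

# The forward model

## Beat timing

R peaks are placed at intervals RR = 60/HR + ε, ε ~ N(0, `hrv_sd`)
(default 0.02 s), each interval snapped to the sample grid so that the
jitter-free case yields exactly identical RR intervals. The default
sampling rate is 1000 Hz; all fiducial annotations are exact at sample
resolution by construction.

## Channel morphologies

Beat templates are parameterized synthetic morphologies chosen for
controllability, not realism:

* **ECG** — a sum of five Gaussians (P, Q, R, S, T) with a 1 mV R peak.
* **BCG** — a Gaussian-enveloped 7 Hz cosine whose central maximum is the
  J wave and whose flanking minima are I and K. A Gaussian envelope (a
  two-sided damped sinusoid) was preferred over a one-sided exponentially
  decaying sinusoid because it is smooth at onset: the zero-phase
  band-pass applied by the pipeline then neither rings nor shifts the
  extrema, and the unit template's J time and J−K amplitude can be
  characterized numerically once per sampling rate and used to place and
  scale each beat exactly.
* **PPG** — a log-normal-rise pulse (peak at 0.18 s, shape 0.45) with a
  smooth cosine taper back to baseline by 0.68 s so consecutive pulses do
  not overlap at the heart rates simulated (range ≈ 48–113 bpm).

## Encoding the vitals

One transit time per beat must explain both pressures, as in a real
single-PTT measurement. The generator therefore drives PWV from systolic
pressure through the subject's ground-truth linear model,
PWV = (SBP − b_s)/a_s, and places the PPG foot of both wavelengths at
J + PTT with PTT = L/PWV; diastolic pressure is encoded only through a
second linear map sharing that same PTT. When session vitals are sampled
(`sample_session_vitals()`), DBP follows the subject's diastolic map at
the session PWV plus an independent deviation of SD 1.5 mm Hg — the
unexplained within-subject variance that bounds how well any single-PTT
estimator can do.

The BCG is scaled so the J−K amplitude equals (SV − c)/g for the
subject's ground-truth SV map, and the PPG AC/DC ratios are set so the
ratio-of-ratios R satisfies SpO₂ = −33.3·R + o, with o the
subject-specific R-curve offset. The slope −33.3 %/R is the literature
value for transmission pulse oximetry; per-subject variation is carried
by the offset alone, reflecting the empirical finding that R-curve slopes
are nearly common across subjects while offsets differ materially at a
thigh measurement site.

The foot annotation is placed using the *same* intersecting-tangent
definition the pipeline uses, characterized numerically on the clean unit
pulse, so the noise-free round trip is exact rather than merely close.

## Fixed physiological parameters

* **PEP** = 0.08 s (SD 0.008 s between subjects, constant within a
  recording). PTT excludes PEP by construction because its proximal
  anchor is the BCG J wave; the value therefore only shifts where in the
  beat window the fiducials fall.
* **Aortic length** = 0.285 × height. The generator and the estimator
  share this anthropometric coefficient; a real deployment would estimate
  it, and any multiplicative error would be absorbed into the per-subject
  BP offset at calibration.
* **Population parameters** (cohort generator): BP slopes a_s ~ N(12, 0.6),
  a_d ~ N(8, 0.4) mm Hg/(m/s); offsets b_s ~ N(60, 5), b_d ~ N(40, 4)
  mm Hg; R-curve offset ~ N(127, 3) %; SV gain ~ N(20, 1.5) mL/N,
  intercept ~ N(10, 4) mL; baseline SBP ~ N(120, 9) mm Hg, HR ~ N(74.3,
  12.4) bpm truncated to [47.8, 113.2], SpO₂ ~ N(97.3, 0.8) %, SV ~
  N(70, 13) mL. Demographics follow the selected cohort preset
  (means/SDs per cohort, BMI always derived). A fully degenerate
  specification (all demographic SDs zero) collapses the physiological
  SDs too, yielding identical subjects.

## Noise model and defaults

Additive white noise per channel (ECG 0.02 mV, BCG 0.05 N, PPG 0.003
a.u.) plus two-component sinusoidal baseline wander (ECG 0.05 mV, BCG
0.2 N, PPG 0.005 a.u., fundamental 0.15 Hz, random phases). These
defaults were chosen once so that the default pipeline clears the
AAMI/ISO compliance margins with roughly 2× headroom or better, and are
not tuned per experiment. Artifacts are injected explicitly:
`motion_burst` (broadband noise on BCG/PPG), `ectopic_beat` (a premature
QRS plus attenuated mechanical complexes, shortening one RR), `dropout`
(all channels zeroed).

# The processing pipeline

1. **R detection** — derivative-energy (Pan-Tompkins-style): band-pass
   0.5–40 Hz, differentiate, square, 150 ms integration window, adaptive
   threshold at 0.25 × the 98th percentile of the energy envelope, 250 ms
   refractory period, peak refinement on the band-passed ECG. Flat or
   non-finite input yields an empty, flagged beat series.
2. **Abnormal-interval removal** — a beat is rejected iff either adjacent
   RR deviates from the running median RR (window 11) by more than 20 %.
   Both beats bounding an abnormal interval are removed because diastolic
   duration and ventricular filling shift beat-by-beat BP and SV. The
   rule reads only the original timings, so it is idempotent.
3. **Recording-level gate** — accept iff ≥ 20 accepted beats, the
   accepted beats span ≥ 30 s, and at most 20 % of 1-s BCG windows have
   RMS above 5× the median window RMS (the motion metric).
4. **Ensemble averaging** — pointwise mean over accepted beats aligned on
   R, window −0.2…+0.8 s truncated to the shortest accepted RR. The BCG
   is band-passed (0.5–20 Hz, zero-phase, reflection-padded `filtfilt`)
   before ensembling; the PPG channels are ensembled *raw*: the ensemble
   itself is the denoiser, and the DC optical level — needed for the
   R-value — must survive. The ECG band-pass exists only for detection.
5. **Fiducials** — J is the global maximum of the BCG ensemble in
   [0.05, 0.40] s after R (ties resolved to the earliest sample for
   determinism), I and K the flanking local minima. The PPG foot uses
   intersecting tangents: the tangent at maximum upslope intersected with
   the horizontal through the pre-systolic minimum. The upslope is
   located first, on a 20 ms moving-average copy (the most wander-robust
   landmark), and the minimum is searched only within 0.12 s before it —
   a shallow pulse (AC/DC ≈ 2 %) otherwise lets residual wander capture
   the global minimum far from the pulse. The method is invariant to
   constant offsets, and the foot is reported at sub-sample resolution.
6. **Estimation** — PTT = foot − J (infrared channel by default), PWV =
   L/PTT, then the calibrated linear maps. `estimate_spo2()` clips to
   (0, 100]; SV is clamped at 0 and flagged if the linear map goes
   negative; CO = SV·HR/1000 with HR from the median accepted RR.

## Calibration

Single-session, as the measurement protocol dictates: BP offsets
b = mean(cuff) − a·mean(PWV) with slopes fixed at the population values;
the SpO₂ offset o = ref − s·r_cal. Every calibrated estimator is exact at
its calibration point. Central-versus-peripheral pressure discrepancies
and site-specific optical differences are deliberately absorbed into
these per-subject offsets. The BP model can be expressed in PWV (default)
or 1/PTT via `pipeline_config(bp_predictor=)`; the two are proportional
given a fixed aortic length, so slopes rescale by L but estimates agree —
covered by a test.

The SV map is population-level (no per-subject session): coefficients are
fit by ordinary least squares of reference SV on measured J−K amplitude
over a disjoint training cohort. This linear form is an explicit stand-in
for published BCG stroke-volume algorithms, which use richer feature sets;
it is not claimed to replicate them.

# Validation-study design

`run_validation_study()` calibrates each subject on session 1 and
evaluates all later sessions against the per-session ground truth; the
generator's true vitals stand in for the cuff/vitals-monitor averages a
clinical protocol would record. The default study sizes mirror the
validation cohorts of the measurement protocol the package models:

* blood pressure — 12 subjects × 10 sessions (108 evaluated recordings);
* SpO₂ — 11 subjects × 9 sessions (88 evaluated recordings);
* stroke volume — 149 single-session recordings (38 normative + 111
  in-clinic demographics) with the population SV fit taken from a
  disjoint 60-recording training cohort.

Each recording is 60 s at 1000 Hz. `scripts/acceptance.R` runs exactly
these studies and writes the Bland-Altman statistics as JSON.

## Statistics conventions

Bland-Altman differences are device − gold; `sd` uses the sample (n−1)
divisor, A_RMS the n divisor (its RMS definition), so
A_RMS² = bias² + sd²·(n−1)/n holds as an internal identity. LoA half-width
is exactly 1.96·sd; an A_RMS bound converts to an LoA by the same factor
under a zero-mean assumption. BMI strata use half-open bins
[low, high): <18.5, [18.5, 25), [25, 30), ≥30. Percent variation between
two calibration slopes uses the mean-magnitude denominator,
100·|s1−s2|/|mean|, rounded to the nearest integer for reporting (the
plausible alternatives — smaller slope or the literature slope as
denominator — agree to within rounding for the slope pairs of interest).

# Numerical choices and degenerate inputs

* Zero-phase filtering uses reflection padding (2 s) to suppress
  `filtfilt` edge transients.
* Tie-breaks in extremum searches always resolve to the earliest sample.
* Fewer than 3 detected beats: all rejected with reason `"too_few"`; an
  all-flat or all-NaN ECG yields an empty flagged beat series; a
  non-pulsatile PPG ensemble (AC ≤ 1e-4·DC) flags the R-value rather
  than emitting one; a non-positive PTT suppresses BP estimates with a
  flag rather than extrapolating.
* Every random draw in simulation derives from an explicit integer seed;
  sub-seeds are deterministic functions of (master seed, subject,
  session) kept below 2³¹.

# What passing these tests does and does not show

The generator emulates the *geometry* of the measurement — beat-locked
morphologies whose timing and amplitudes encode the vitals, stationary
white noise, slow baseline wander, simple artifact classes. It does not
emulate: real inter-beat morphology variability, respiration-coupled
amplitude modulation, posture and contact-pressure effects, skin-pigment
optics, low-amplitude heart-failure BCG morphologies, or PEP changes
within a recording. Parameter-recovery and compliance results on
synthetic data therefore validate the *software chain* — detection,
gating, averaging, fiducial geometry, calibration algebra and the
validation statistics — under the stated noise model; they are not
evidence that a physical device meets AAMI/ISO criteria on humans.

Known limitations: the SV model is a linear stand-in; absolute SpO₂
without per-subject calibration is out of scope (only relative changes,
`spo2_change()`); hypoxia-range pigment correction and PEP estimation are
out of scope; four individual load cells are not simulated, only their
sum, since all in-scope processing uses the summed force.
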
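# seatvitals

Simulation and analysis of the signals produced by unobtrusive, seat-based
cardiovascular monitors: a synchronized single-lead electrocardiogram (ECG),
a ballistocardiogram (BCG, the body-reaction force of cardiac ejection) and
a dual-wavelength photoplethysmogram (PPG). From these three channels such
devices estimate systolic and diastolic blood pressure, stroke volume (SV),
cardiac output (CO) and peripheral oxygen saturation (SpO₂) — without a
cuff, and with a single per-subject calibration session.

The package is aimed at researchers developing or evaluating cuffless
vital-sign algorithms. Because paired seat/gold-standard data are hard to
obtain, it ships a forward generator that produces coupled ECG/BCG/PPG
recordings whose waveform features *encode known ground-truth vitals*, so
every stage of the processing chain can be tested quantitatively.

## The models at the core

**Blood pressure from pulse transit time.** The aortic pulse transit time
(PTT) is the interval from the BCG J wave (aortic ejection) to the foot of
the peripheral PPG pulse; it deliberately excludes the pre-ejection period
(PEP), which an ECG-referenced pulse-arrival time would contaminate. With
an aortic length estimate L = 0.285·height, the pulse wave velocity is
PWV = L / PTT, and pressure follows a linear model with population slopes
and a per-subject offset fixed by one calibration session:

    SBP = a_s · PWV + b_s,    DBP = a_d · PWV + b_d,
    b = mean(cuff) − a · mean(PWV)   (single-session calibration)

**SpO₂ from the ratio of ratios.** Each PPG wavelength contributes a
pulsatile (AC) and baseline (DC) amplitude; the R-value is
R = (AC_red/DC_red)/(AC_ir/DC_ir), mapped to saturation by the linear
R-curve SpO₂ = s·R + o with the population slope s = −33.3 %/R and a
subject-specific offset o from a single-point calibration.

**Stroke volume from BCG amplitude.** The ensemble-averaged BCG J−K
amplitude (N) maps linearly to SV (mL) with population coefficients fit on
training data; CO = SV·HR/1000 (L/min). This linear form is a deliberately
simple stand-in for published BCG stroke-volume algorithms.

**Device-validation statistics.** Bland-Altman bias/SD/limits of agreement
(LoA = bias ± 1.96·SD), root-mean-square error (A_RMS), the AAMI
blood-pressure criterion (|bias| ≤ 5 mm Hg, SD ≤ 8 mm Hg), the ISO
pulse-oximetry criterion (A_RMS ≤ 3.5 %), and BMI stratification.

## Worked example

```r
library(seatvitals)

subject <- subject_profile("S001", age = 25, height = 175, weight = 75)
vitals  <- true_vitals(sbp = 120, dbp = 80, sv = 70, spo2 = 97, hr = 74.3)
rec     <- generate_recording(subject, vitals, duration = 60, seed = 7)
rec
#> <recording S001: 60 s @ 1000 Hz, channels ecg/bcg/ppg_red/ppg_ir, 216 annotations>

# single-session calibration against cuff/oximeter references
model <- calibrate_subject(rec, vitals, subject$height)
model
#> <calibration_model for S001>
#>   BP (pwv): sbp = 12.00*x + 62.40239, dbp = 8.00*x + 41.60159
#>   SpO2: -33.3*R + 126.9473 ; SV: 10.0 + 20.0*JK ; L = 0.49875 m

# a later session at a different physiological state
vit2 <- true_vitals(sbp = 131, dbp = 87.3, sv = 75, spo2 = 95, hr = 71)
rec2 <- generate_recording(subject, vit2, duration = 60, seed = 8)
out  <- process_recording(rec2, model, recording_id = "S001_s02")
out$quality
#> <quality_report: accepted, 70/70 beats accepted>
round(out$estimate[, c("ptt", "pwv", "sbp", "dbp", "spo2", "sv", "co", "hr")], 2)
#>    ptt  pwv    sbp   dbp spo2   sv   co    hr
#> 1 0.09 5.47 128.02 85.35 95.3 74.2 5.28 71.17
```

The estimates track the true session vitals (131/87.3 mm Hg, 95 %, 75 mL)
to within a few mm Hg / tenths of a percent at the default channel noise;
the residual scatter is what the validation statistics quantify:

```r
ba <- bland_altman(c(118.1, 124.9, 131.2), c(120, 124, 130))
ba
#> <bland_altman: n=3, bias 0.07 (SD 1.71), LoA [-3.28, 3.42], A_RMS 1.40>
check_compliance(ba, "AAMI_BP")
#> <AAMI_BP: PASS (margin 4.93)>
```

`simulate_study()` / `run_validation_study()` / `evaluate_sv_study()`
orchestrate whole multi-subject, multi-session studies (calibrate on the
first session, estimate the rest, compare to ground truth). A thin CLI
wrapping these functions is installed at `inst/cli/seatvitals`
(`simulate | calibrate | process | validate`).

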
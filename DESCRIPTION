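Package: seatvitals
Title: Synthetic Cardiomechanical Signals and Cuffless Vital-Sign Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of coupled electrocardiogram (ECG),
    ballistocardiogram (BCG) and dual-wavelength photoplethysmogram (PPG)
    recordings of the kind produced by unobtrusive seat-based cardiovascular
    monitors. A forward generator encodes configurable ground-truth vitals
    (blood pressure via a pulse-transit-time/pulse-wave-velocity model,
    stroke volume via BCG J-K amplitude, peripheral oxygen saturation via the
    ratio-of-ratios R-curve) into multichannel waveforms with noise, baseline
    wander and beat-level artifacts. A processing pipeline performs QRS
    detection, abnormal-interval beat removal, recording-level quality gating,
    ECG-referenced ensemble averaging, BCG I-J-K and PPG-foot fiducial
    extraction, and per-subject single-session calibration to estimate
    systolic/diastolic blood pressure, SpO2, stroke volume and cardiac
    output. Device-validation statistics (Bland-Altman bias/SD/limits of
    agreement, root-mean-square error, AAMI and ISO compliance checks, BMI
    stratification) close the loop for end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
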
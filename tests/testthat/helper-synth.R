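# Shared fixtures, built once per test run.

default_subject <- function() {
  subject_profile("S1", age = 25, height = 175, weight = 75)
}

default_vitals <- function(sbp = 120, dbp = 80, sv = 70, spo2 = 97,
                           hr = 74.3, hrv_sd = 0.02) {
  true_vitals(sbp, dbp, sv, spo2, hr, hrv_sd)
}

# Consistent diastolic pressure for a subject at a given systolic state,
# so the single transit time explains both pressures.
consistent_dbp <- function(subject, sbp) {
  pwv <- (sbp - subject$bp_offset_s) / subject$bp_slope_s
  subject$bp_slope_d * pwv + subject$bp_offset_d
}

.fixture_env <- new.env(parent = emptyenv())

# Clean (noise-free, jitter-free) 60 s recording reused across files.
clean_recording <- function() {
  if (is.null(.fixture_env$clean)) {
    .fixture_env$clean <- generate_recording(
      default_subject(), default_vitals(hrv_sd = 0),
      duration = 60, fs = 1000, noise = noise_none(), seed = 7)
  }
  .fixture_env$clean
}

clean_features <- function() {
  if (is.null(.fixture_env$clean_feat)) {
    .fixture_env$clean_feat <- extract_features(clean_recording())
  }
  .fixture_env$clean_feat
}

# Noise-free SV coefficient fit on a small amplitude sweep (shared).
clean_sv_coef <- function() {
  if (is.null(.fixture_env$sv_coef)) {
    subj <- default_subject()
    jk <- sv <- numeric(0)
    for (s in c(50, 65, 80, 95)) {
      r <- generate_recording(subj, default_vitals(sv = s, hrv_sd = 0),
                              duration = 40, fs = 1000,
                              noise = noise_none(), seed = 100 + s)
      f <- extract_features(r)$features
      jk <- c(jk, f$jk_amplitude); sv <- c(sv, s)
    }
    .fixture_env$sv_coef <- fit_sv_model(jk, sv)
  }
  .fixture_env$sv_coef
}
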
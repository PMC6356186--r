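test_that("cohort demographics follow the specification", {
  sp <- cohort_spec("spo2")
  cohort <- generate_cohort(1000, sp, seed = 11)
  age <- vapply(cohort, `[[`, numeric(1), "age")
  weight <- vapply(cohort, `[[`, numeric(1), "weight")
  height <- vapply(cohort, `[[`, numeric(1), "height")
  se <- function(sd) sd / sqrt(1000)
  expect_lt(abs(mean(age) - sp$age_mean), 3 * se(sp$age_sd))
  expect_lt(abs(mean(weight) - sp$weight_mean), 3 * se(sp$weight_sd))
  expect_lt(abs(mean(height) - sp$height_mean), 3 * se(sp$height_sd))
  # BMI derived, never sampled
  for (s in cohort[1:20])
    expect_equal(s$bmi, s$weight / (s$height / 100)^2)
  expect_true(all(weight <= 180))
})

test_that("degenerate spec yields identical profiles; cohorts are reproducible", {
  sp0 <- cohort_spec("custom", age_sd = 0, weight_sd = 0, height_sd = 0,
                     male_frac = 1)
  c3 <- generate_cohort(3, sp0, seed = 5)
  c3b <- lapply(c3, function(s) { s$subject_id <- "X"; s })
  expect_equal(c3b[[1]], c3b[[2]])
  expect_equal(c3b[[2]], c3b[[3]])
  expect_equal(c3[[1]]$age, sp0$age_mean)
  expect_equal(c3[[1]]$height, sp0$height_mean)
  # determinism
  expect_identical(generate_cohort(8, cohort_spec("dbp"), seed = 3),
                   generate_cohort(8, cohort_spec("dbp"), seed = 3))
  # invalid inputs
  expect_error(generate_cohort(0), "positive")
  expect_error(cohort_spec("custom", age_sd = -1), "SD")
})

test_that("annotated beat count matches the configured heart rate", {
  rec <- clean_recording()   # HR 74.3, 60 s
  n_r <- sum(rec$annotations$event_type == "r_peak")
  expect_lte(abs(n_r - round(60 * 74.3 / 60)), 1)
})

test_that("jitter off makes all RR intervals identical", {
  rec <- clean_recording()
  rr <- diff(sort(rec$annotations$time_s[rec$annotations$event_type == "r_peak"]))
  expect_lt(diff(range(rr)), 1e-9 + 1e-12)  # snapped to a common grid value
})

test_that("recording generation is deterministic in (subject, vitals, seed)", {
  subj <- default_subject()
  vit <- default_vitals()
  r1 <- generate_recording(subj, vit, duration = 12, fs = 500, seed = 21)
  r2 <- generate_recording(subj, vit, duration = 12, fs = 500, seed = 21)
  expect_identical(r1, r2)
})

test_that("generator transit time is strictly decreasing in systolic pressure", {
  subj <- default_subject()
  sbps <- c(100, 110, 120, 135, 150)
  ptts <- vapply(sbps, function(sbp) {
    rec <- generate_recording(subj, default_vitals(sbp = sbp, hrv_sd = 0),
                              duration = 10, fs = 500,
                              noise = noise_none(), seed = 2)
    ann <- rec$annotations
    j <- sort(ann$time_s[ann$event_type == "j_wave"])
    f <- sort(ann$time_s[ann$event_type == "ppg_foot"])
    mean(f - j)
  }, numeric(1))
  expect_true(all(diff(ptts) < 0))
  # matches direct evaluation of the PTT formula
  direct <- subj$aortic_length * subj$bp_slope_s / (sbps - subj$bp_offset_s)
  expect_equal(ptts, direct, tolerance = 1e-10)
})

test_that("generator R-value is strictly decreasing in SpO2", {
  subj <- default_subject()
  rs <- vapply(c(90, 94, 98), function(s) {
    generate_recording(subj, default_vitals(spo2 = s), duration = 10,
                       fs = 500, noise = noise_none(), seed = 2)$truth$r_value
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
})

test_that("physiologically impossible inputs are rejected with diagnostics", {
  subj <- default_subject()
  expect_error(true_vitals(80, 90, 70, 97, 74), "sbp")
  expect_error(true_vitals(120, 80, 70, 105, 74), "spo2")
  expect_error(true_vitals(120, 80, 70, 97, 20), "hr")
  # sbp below the subject's BP-model offset implies non-positive PWV
  expect_error(generate_recording(subj, true_vitals(55, 40, 70, 97, 74)),
               "PWV")
  expect_error(subject_profile("X", 30, 175, 190), "180")
  expect_error(generate_recording(subj, default_vitals(), duration = 5),
               "duration")
})

test_that("round trip with zero noise reproduces closed-form fiducial values", {
  rec <- clean_recording()
  f <- clean_features()$features
  tr <- rec$truth
  fs <- rec$fs
  expect_lt(abs((f$foot_time - f$j_time) - tr$ptt), 1 / fs)
  expect_lt(abs(f$jk_amplitude - tr$jk_amplitude) / tr$jk_amplitude, 0.05)
  expect_lt(abs(f$r_value - tr$r_value) / tr$r_value, 0.01)
  expect_lt(abs(f$ac_ir - tr$ac_ir) / tr$ac_ir, 0.02)
  expect_lt(abs(f$dc_ir - tr$dc_ir) / tr$dc_ir, 0.02)
})

test_that("empty artifact spec leaves the recording unchanged sample-for-sample", {
  rec <- generate_recording(default_subject(), default_vitals(),
                            duration = 10, fs = 500, seed = 3)
  expect_identical(inject_artifacts(rec, data.frame()), rec)
})

test_that("one ectopic creates exactly one short RR interval in the annotations", {
  rec <- generate_recording(default_subject(), default_vitals(),
                            duration = 20, fs = 500, seed = 4)
  r_ann <- sort(rec$annotations$time_s[rec$annotations$event_type == "r_peak"])
  t_ect <- r_ann[8] + 0.85 * (r_ann[9] - r_ann[8])
  rec2 <- inject_artifacts(rec, data.frame(type = "ectopic_beat",
                                           onset = t_ect, duration = 0,
                                           magnitude = 0.8))
  r2 <- sort(rec2$annotations$time_s[rec2$annotations$event_type == "r_peak"])
  rr2 <- diff(r2)
  expect_equal(length(r2), length(r_ann) + 1)
  # late-coupled premature beat: only the ectopic-to-next interval is short
  expect_equal(sum(rr2 < 0.8 * median(rr2)), 1)
})

test_that("artifact windows outside the recording are rejected", {
  rec <- generate_recording(default_subject(), default_vitals(),
                            duration = 10, fs = 500, seed = 5)
  expect_error(inject_artifacts(rec, data.frame(type = "motion_burst",
                                                onset = 8, duration = 5,
                                                magnitude = 1)),
               "outside")
})
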
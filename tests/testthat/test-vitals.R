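test_that("aortic length estimate is linear in height with a guard on range", {
  expect_equal(estimate_aortic_length(175.2), 0.499, tolerance = 1e-3)
  expect_equal(estimate_aortic_length(200) / estimate_aortic_length(100), 2)
  expect_error(estimate_aortic_length(90), "height")
  expect_error(estimate_aortic_length(175, coef = 0), "positive")
})

test_that("PTT/PWV arithmetic and flags", {
  out <- compute_ptt_pwv(0.10, 0.20, 0.5)
  expect_equal(out$ptt, 0.10)
  expect_equal(out$pwv, 5.0)
  out2 <- compute_ptt_pwv(0.10, 0.30, 0.5)
  expect_equal(out2$pwv, out$pwv / 2)
  bad <- compute_ptt_pwv(0.20, 0.10, 0.5)
  expect_true(is.na(bad$pwv))
  expect_true("nonpositive_ptt" %in% bad$flags)
})

test_that("single-session BP calibration is exact at the calibration point", {
  cal <- data.frame(pwv = 5, cuff_sbp = 120, cuff_dbp = 80)
  model <- calibrate_bp(cal, population_slopes = c(12, 8),
                        model = calibration_model(aortic_length = 0.5))
  expect_equal(model$bp_offset_s, 60)
  expect_equal(model$bp_offset_d, 40)
  est <- estimate_bp(model, 5)
  expect_equal(est$sbp, 120)
  expect_equal(est$dbp, 80)
  est2 <- estimate_bp(model, 5.5)
  expect_equal(est2$sbp, 126)
  expect_equal(est2$dbp, 84)
  # degenerate slopes: estimator constant at the calibration BP
  m0 <- calibrate_bp(cal, population_slopes = c(0, 0),
                     model = calibration_model(aortic_length = 0.5))
  expect_equal(estimate_bp(m0, 9)$sbp, 120)
  expect_error(calibrate_bp(data.frame()), "empty")
  expect_error(estimate_bp(calibration_model(aortic_length = 0.5), 5),
               "calibrated")
})

test_that("BP estimate is strictly increasing in PWV for positive slopes", {
  model <- calibrate_bp(data.frame(pwv = 5, cuff_sbp = 120, cuff_dbp = 80),
                        model = calibration_model(aortic_length = 0.5))
  sbps <- vapply(seq(3, 7, by = 0.5), function(v) estimate_bp(model, v)$sbp,
                 numeric(1))
  expect_true(all(diff(sbps) > 0))
})

test_that("the inverse-PTT predictor gives the same estimates after recalibration", {
  subj <- default_subject()
  cfg_inv <- pipeline_config(bp_predictor = "inverse_ptt",
                             bp_slopes = c(12 * subj$aortic_length,
                                           8 * subj$aortic_length))
  cal_vit <- default_vitals(hrv_sd = 0)
  cal_rec <- clean_recording()
  m_pwv <- calibrate_subject(cal_rec, cal_vit, subj$height, pipeline_config())
  m_inv <- calibrate_subject(cal_rec, cal_vit, subj$height, cfg_inv)
  sbp_t <- 132
  test_rec <- generate_recording(
    subj, true_vitals(sbp_t, consistent_dbp(subj, sbp_t), 70, 97, 74.3,
                      hrv_sd = 0),
    duration = 30, noise = noise_none(), seed = 31)
  e1 <- process_recording(test_rec, m_pwv)$estimate
  e2 <- process_recording(test_rec, m_inv, cfg_inv)$estimate
  expect_equal(e1$sbp, e2$sbp, tolerance = 1e-6)
  expect_equal(e1$dbp, e2$dbp, tolerance = 1e-6)
})

test_that("R-value arithmetic and ratio invariance", {
  expect_equal(compute_r_value(0.02, 1, 0.02, 1), 1)
  expect_equal(compute_r_value(0.02, 1, 0.04, 1), 0.5)
  expect_equal(compute_r_value(3 * 0.02, 3 * 1.3, 0.04, 1),
               compute_r_value(0.02, 1.3, 0.04, 1))
  expect_error(compute_r_value(0, 1, 0.04, 1), "positive")
})

test_that("single-point SpO2 calibration is exact and clipped sensibly", {
  model <- calibrate_spo2(0.9, 97, slope = -33.3)
  expect_equal(model$spo2_offset, 126.97)
  expect_equal(estimate_spo2(model, 0.9), 97)
  expect_equal(estimate_spo2(model, 0.99), 94.003, tolerance = 1e-6)
  rs <- seq(0.85, 1.2, by = 0.05)   # below 100% so clipping is inactive
  expect_true(all(diff(estimate_spo2(model, rs)) < 0))
  expect_lte(max(estimate_spo2(model, 0.2)), 100)
  expect_error(calibrate_spo2(0.9, 97, slope = 10), "negative")
  expect_error(estimate_spo2(calibration_model(), 0.9), "calibrated")
  expect_equal(spo2_change(1.0, 0.9), -3.33)
})

test_that("SV estimation is linear in J-K amplitude with guards", {
  m <- calibration_model(sv_intercept = 0, sv_gain = 20)
  expect_equal(estimate_sv(2, m)$sv, 40)
  expect_equal(estimate_sv(4, m)$sv, 80)
  m2 <- calibration_model(sv_intercept = 55, sv_gain = 1e-9)
  expect_equal(estimate_sv(2, m2)$sv, estimate_sv(9, m2)$sv, tolerance = 1e-6)
  out <- estimate_sv(NA_real_, m)
  expect_true(is.na(out$sv))
  expect_true("no_bcg_fiducials" %in% out$flags)
  expect_error(calibration_model(sv_gain = -1), "positive")
})

test_that("cardiac output is the SV-HR product in L/min", {
  expect_equal(compute_co(70, 70), 4.9)
  expect_equal(compute_co(0, 70), 0)
  expect_equal(compute_co(70, 140), 2 * compute_co(70, 70))
  expect_error(compute_co(-1, 70), "sv")
  expect_error(compute_co(70, 0), "hr")
})

test_that("calibration round trip recovers the generator R-curve offset", {
  subj <- default_subject()
  rec <- clean_recording()
  model <- calibrate_subject(rec, default_vitals(hrv_sd = 0), subj$height,
                             pipeline_config())
  expect_lt(abs(model$spo2_offset - subj$r_curve_offset) / subj$r_curve_offset,
            0.005)
})

test_that("calibration files round-trip losslessly", {
  model <- calibration_model("S9", aortic_length = 0.51, bp_offset_s = 61.25,
                             bp_offset_d = 40.125, spo2_offset = 126.97)
  path <- tempfile(fileext = ".cal")
  write_calibration(model, path)
  model2 <- read_calibration(path)
  expect_equal(model2, model)
})
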
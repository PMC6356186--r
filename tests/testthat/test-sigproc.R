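test_that("R detection matches annotations exactly on a clean recording", {
  rec <- clean_recording()
  beats <- detect_r_peaks(rec$ecg, rec$fs)
  truth <- sort(rec$annotations$time_s[rec$annotations$event_type == "r_peak"])
  expect_equal(length(beats$r_times), length(truth))
  expect_lt(max(abs(beats$r_times - truth)), 0.010)
})

test_that("flat or non-finite ECG yields an empty flagged beat series", {
  for (x in list(rep(0, 3000), rep(NA_real_, 3000), rep(2.5, 3000))) {
    b <- detect_r_peaks(x, 500)
    expect_equal(length(b$r_times), 0)
    expect_true(b$flagged)
  }
  expect_error(detect_r_peaks(rep(0, 100), 500), "2 s")
})

test_that("detection sensitivity and PPV are >= 99% at default noise", {
  subj <- default_subject()
  tp <- fp <- fn <- 0
  for (k in 1:100) {
    vit <- default_vitals(hr = 55 + (k %% 5) * 10)
    rec <- generate_recording(subj, vit, duration = 30, fs = 500, seed = k)
    beats <- detect_r_peaks(rec$ecg, rec$fs)
    truth <- sort(rec$annotations$time_s[rec$annotations$event_type == "r_peak"])
    matched <- vapply(truth, function(t0) any(abs(beats$r_times - t0) < 0.05),
                      logical(1))
    tp <- tp + sum(matched); fn <- fn + sum(!matched)
    fp <- fp + sum(vapply(beats$r_times, function(t0)
      !any(abs(truth - t0) < 0.05), logical(1)))
  }
  expect_gte(tp / (tp + fn), 0.99)
  expect_gte(tp / (tp + fp), 0.99)
})

test_that("regular RR sequences pass the abnormal-interval filter untouched", {
  beats <- seatvitals:::new_beat_series(seq(0, by = 0.8, length.out = 13))
  out <- filter_abnormal_beats(beats)
  expect_true(all(out$accepted))
  expect_identical(out$r_times, beats$r_times)
})

test_that("a long interval rejects exactly its two bounding beats", {
  rr <- c(rep(0.8, 6), 1.3, rep(0.8, 6))
  beats <- seatvitals:::new_beat_series(cumsum(c(0, rr)))
  out <- filter_abnormal_beats(beats, tolerance = 0.20)
  rejected <- which(!out$accepted)
  expect_equal(rejected, c(7L, 8L))   # beats bounding the 1.3 s interval
  expect_true(all(out$rejection_reason[rejected] == "abnormal_interval"))
})

test_that("abnormal-interval filtering is idempotent", {
  set.seed(42)
  for (k in 1:10) {
    rr <- 0.8 + rnorm(30, 0, 0.1)
    beats <- seatvitals:::new_beat_series(cumsum(c(0, abs(rr))))
    once <- filter_abnormal_beats(beats)
    twice <- filter_abnormal_beats(once)
    expect_identical(once, twice)
  }
})

test_that("fewer than three beats are all rejected as too few", {
  b <- filter_abnormal_beats(seatvitals:::new_beat_series(c(0, 0.8)))
  expect_true(all(!b$accepted))
  expect_true(all(b$rejection_reason == "too_few"))
})

test_that("recording-level gate accepts clean recordings and rejects short/dropout ones", {
  rec <- clean_recording()
  ex <- clean_features()
  expect_true(ex$quality$recording_accepted)
  expect_gte(ex$quality$n_beats_accepted, 20)

  short <- generate_recording(default_subject(), default_vitals(),
                              duration = 12, fs = 500, seed = 9)
  b <- filter_abnormal_beats(detect_r_peaks(short$ecg, short$fs))
  q <- assess_recording(short, b)
  expect_false(q$recording_accepted)
  expect_true("too_short" %in% q$reasons)

  dropped <- inject_artifacts(short, data.frame(type = "dropout", onset = 0,
                                                duration = 12, magnitude = 0))
  bd <- detect_r_peaks(dropped$ecg, dropped$fs)
  qd <- assess_recording(dropped, bd)
  expect_false(qd$recording_accepted)
})

test_that("ensemble of identical noise-free beats equals a single beat", {
  rec <- clean_recording()
  beats <- detect_r_peaks(rec$ecg, rec$fs)
  ens <- ensemble_average(rec, beats, "bcg", window = c(0.1, 0.5))
  i0 <- round(beats$r_times[5] * rec$fs) + 1
  offs <- round(-0.1 * rec$fs):round(0.5 * rec$fs)
  expect_equal(ens$amplitude, rec$bcg[i0 + offs], tolerance = 1e-6)
})

test_that("ensemble averaging attenuates white noise by the 1/sqrt(N) law", {
  fs <- 200
  beat <- sin(2 * pi * 5 * seq(0, 0.5, by = 1 / fs))
  r_times <- seq(1, by = 1, length.out = 64)
  n <- 66 * fs
  clean <- numeric(n)
  for (r in r_times) {
    idx <- round(r * fs) + seq_along(beat)
    clean[idx] <- clean[idx] + beat
  }
  sigma <- 0.5
  resid_sd <- vapply(1:200, function(s) {
    set.seed(s)
    rec <- seatvitals:::new_recording(fs, numeric(n), clean + rnorm(n, 0, sigma),
                                      numeric(n) + 1, numeric(n) + 1,
                                      n / fs, "X")
    beats <- seatvitals:::new_beat_series(r_times)
    ens <- ensemble_average(rec, beats, "bcg", window = c(0.2, 0.8))
    truth <- ensemble_average(
      seatvitals:::new_recording(fs, numeric(n), clean, numeric(n) + 1,
                                 numeric(n) + 1, n / fs, "X"),
      beats, "bcg", window = c(0.2, 0.8))
    sd(ens$amplitude - truth$amplitude)
  }, numeric(1))
  expect_lt(abs(mean(resid_sd) - sigma / 8) / (sigma / 8), 0.20)
})

test_that("rejected beats cannot influence the ensemble", {
  rec <- clean_recording()
  beats <- filter_abnormal_beats(detect_r_peaks(rec$ecg, rec$fs))
  # reject beats 2-4 so no accepted beat's window covers beat 3's samples
  beats$accepted[2:4] <- FALSE
  ens1 <- ensemble_average(rec, beats, "bcg")
  rec2 <- rec
  i0 <- round(beats$r_times[3] * rec$fs) + 1
  rec2$bcg[i0 + (-50:50)] <- 99
  ens2 <- ensemble_average(rec2, beats, "bcg")
  expect_identical(ens1$amplitude, ens2$amplitude)
})

test_that("BCG fiducials recover the annotated J wave and scale linearly", {
  rec <- clean_recording()
  beats <- detect_r_peaks(rec$ecg, rec$fs)
  ens <- ensemble_average(rec, beats, "bcg", band = c(0.5, 20))
  fid <- locate_bcg_fiducials(ens)
  expect_lt(abs(fid$bcg_j$time - default_subject()$pep), 1 / rec$fs + 1e-9)
  expect_true(fid$bcg_i$time < fid$bcg_j$time)
  expect_true(fid$bcg_j$time < fid$bcg_k$time)
  expect_gte(fid$jk_amplitude, 0)
  # positive scaling: amplitudes scale, times unchanged
  for (sc in c(2, 0.3)) {
    ens_s <- ens; ens_s$amplitude <- sc * ens$amplitude
    fid_s <- locate_bcg_fiducials(ens_s)
    expect_equal(fid_s$jk_amplitude, sc * fid$jk_amplitude)
    expect_identical(fid_s$bcg_j$time, fid$bcg_j$time)
    expect_identical(fid_s$bcg_k$time, fid$bcg_k$time)
  }
})

test_that("PPG foot is recovered within 5 ms, precedes the peak, and is offset-invariant", {
  rec <- clean_recording()
  beats <- detect_r_peaks(rec$ecg, rec$fs)
  ens <- ensemble_average(rec, beats, "ppg_ir")
  foot <- locate_ppg_foot(ens)
  truth_foot <- default_subject()$pep + rec$truth$ptt
  expect_lt(abs(foot - truth_foot), 0.005)
  peak_t <- ens$rel_time[which.max(ens$amplitude)]
  expect_lt(foot, peak_t)
  ens_off <- ens; ens_off$amplitude <- ens$amplitude + 5
  expect_equal(locate_ppg_foot(ens_off), foot)
})

test_that("AC/DC measurement matches known amplitudes and is gain-invariant", {
  rec <- clean_recording()
  beats <- detect_r_peaks(rec$ecg, rec$fs)
  ens <- ensemble_average(rec, beats, "ppg_ir")
  acdc <- measure_ppg_ac_dc(ens)
  expect_lt(abs(acdc$ac - rec$truth$ac_ir) / rec$truth$ac_ir, 0.02)
  expect_lt(abs(acdc$dc - rec$truth$dc_ir) / rec$truth$dc_ir, 0.02)
  ens2 <- ens; ens2$amplitude <- 2 * ens$amplitude
  acdc2 <- measure_ppg_ac_dc(ens2)
  expect_equal(acdc2$ac / acdc2$dc, acdc$ac / acdc$dc, tolerance = 1e-12)
  # constant signal: ac = 0, dc = level, flagged non-pulsatile
  ens_const <- ens; ens_const$amplitude <- rep(2, length(ens$amplitude))
  acdc_c <- measure_ppg_ac_dc(ens_const)
  expect_equal(acdc_c$ac, 0)
  expect_equal(acdc_c$dc, 2)
  expect_true("non_pulsatile" %in% acdc_c$flags)
  ens_neg <- ens; ens_neg$amplitude <- ens$amplitude - 10
  expect_error(measure_ppg_ac_dc(ens_neg), "DC")
})
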
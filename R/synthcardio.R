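# Forward generator: subjects, ground-truth vitals, and coupled
# ECG/BCG/PPG recordings whose waveform features encode those vitals.

#' Population R-curve slope used to map the ratio-of-ratios to SpO2
#'
#' Literature slope of the pulse-oximetry calibration curve, in percent
#' saturation per unit R.  Per-subject variation is carried by the offset
#' only; the slope is shared across the population.
#' @export
SPO2_SLOPE_DEFAULT <- -33.3

#' Subject demographics specification
#'
#' Means and standard deviations for the demographic fields a cohort is
#' drawn from, plus the fraction of male subjects.  Presets reproduce the
#' validation cohorts of a seat-based monitor study (age/weight/height in
#' years/kg/cm).
#'
#' @param cohort one of `"dbp"`, `"sbp"`, `"sv_normative"`, `"sv_clinic"`,
#'   `"spo2"`, or `"custom"`.
#' @param age_mean,age_sd,weight_mean,weight_sd,height_mean,height_sd,male_frac
#'   overrides for `"custom"` (ignored otherwise unless supplied).
#' @return a list with the demographic means/SDs.
#' @export
cohort_spec <- function(cohort = c("spo2", "dbp", "sbp", "sv_normative",
                                   "sv_clinic", "custom"),
                        age_mean = 22.5, age_sd = 2.9,
                        weight_mean = 77.6, weight_sd = 12.9,
                        height_mean = 173.9, height_sd = 9.5,
                        male_frac = 10 / 11) {
  cohort <- match.arg(cohort)
  preset <- switch(cohort,
    dbp          = list(22.5, 2.8, 76.1, 13.5, 173.6, 9.3, 9 / 12),
    sbp          = list(22.6, 2.9, 76.7, 13.9, 175.2, 7.9, 9 / 11),
    sv_normative = list(24.5, 5.6, 73.3, 21.1, 171.8, 7.6, 22 / 38),
    sv_clinic    = list(55.7, 16.4, 81.3, 19.5, 170.6, 10.3, 59 / 111),
    spo2         = list(22.5, 2.9, 77.6, 12.9, 173.9, 9.5, 10 / 11),
    custom       = list(age_mean, age_sd, weight_mean, weight_sd,
                        height_mean, height_sd, male_frac)
  )
  names(preset) <- c("age_mean", "age_sd", "weight_mean", "weight_sd",
                     "height_mean", "height_sd", "male_frac")
  sds <- unlist(preset[c("age_sd", "weight_sd", "height_sd")])
  if (any(sds < 0)) stop("demographic SDs must be >= 0")
  preset
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Construct a subject profile
#'
#' Holds demographics plus the subject-side ground-truth parameters of the
#' forward model: aortic length, pre-ejection period, the per-pressure
#' PWV-to-BP linear maps, the subject's R-curve offset, and the BCG-force to
#' stroke-volume map.  `bmi` is always derived from height and weight.
#'
#' @param subject_id character id.
#' @param age,height,weight years / cm / kg; weight must not exceed 180 kg.
#' @param sex `"M"` or `"F"`.
#' @param aortic_length m; default derived from height (0.285 * height in m).
#' @param pep pre-ejection period, s.
#' @param r_curve_offset subject-specific SpO2 intercept, percent.
#' @param bp_slope_s,bp_offset_s,bp_slope_d,bp_offset_d ground-truth linear
#'   maps from PWV (m/s) to systolic/diastolic pressure (mm Hg).
#' @param sv_gain,sv_intercept ground-truth map from BCG J-K amplitude (N)
#'   to stroke volume (mL): sv = sv_intercept + sv_gain * jk.
#' @param baseline optional list of subject-level baseline vitals used by
#'   [sample_session_vitals()].
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, age, height, weight, sex = "M",
                            aortic_length = 0.285 * height / 100,
                            pep = 0.08, r_curve_offset = 127,
                            bp_slope_s = 12, bp_offset_s = 60,
                            bp_slope_d = 8, bp_offset_d = 40,
                            sv_gain = 20, sv_intercept = 10,
                            baseline = NULL) {
  stopifnot(height > 0, weight > 0, aortic_length > 0, pep > 0)
  if (weight > 180) stop("weight exceeds the 180 kg exclusion limit")
  structure(list(
    subject_id = as.character(subject_id), age = age, sex = sex,
    height = height, weight = weight,
    bmi = weight / (height / 100)^2,
    aortic_length = aortic_length, pep = pep,
    r_curve_offset = r_curve_offset,
    bp_slope_s = bp_slope_s, bp_offset_s = bp_offset_s,
    bp_slope_d = bp_slope_d, bp_offset_d = bp_offset_d,
    sv_gain = sv_gain, sv_intercept = sv_intercept,
    baseline = baseline
  ), class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile %s: %s, %.0f y, %.1f cm, %.1f kg, BMI %.1f>\n",
              x$subject_id, x$sex, x$age, x$height, x$weight, x$bmi))
  invisible(x)
}

#' Generate a cohort of subject profiles
#'
#' Demographics are drawn from truncated normal distributions at the
#' specification's means/SDs; BMI is derived, never sampled.  Ground-truth
#' physiological parameters (BP model slopes and offsets, R-curve offset,
#' stroke-volume gain, baseline vitals) are drawn from population
#' distributions documented in the methods vignette.
#'
#' A fully degenerate specification (all demographic SDs zero) collapses
#' the physiological population SDs as well, yielding identical subjects
#' at the population means.  Sex is assigned deterministically so a cohort
#' reproduces its specification's male count exactly.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param demographics_spec a [cohort_spec()].
#' @param seed integer seed; the cohort is reproducible for a fixed seed.
#' @param id_prefix prefix for subject ids.
#' @return a list of [subject_profile()] objects.
#' @export
generate_cohort <- function(n_subjects, demographics_spec = cohort_spec("spo2"),
                            seed = 1L, id_prefix = "S") {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("n_subjects must be a positive count")
  n_subjects <- as.integer(n_subjects)
  sp <- demographics_spec
  if (any(unlist(sp[c("age_sd", "weight_sd", "height_sd")]) < 0))
    stop("demographic SDs must be >= 0")
  set.seed(as.integer(seed))
  k <- all(unlist(sp[c("age_sd", "weight_sd", "height_sd")]) == 0)
  k <- if (k) 0 else 1                      # degenerate spec -> identical subjects
  age <- rnorm_trunc(n_subjects, sp$age_mean, sp$age_sd, 16, 100)
  weight <- rnorm_trunc(n_subjects, sp$weight_mean, sp$weight_sd, 35, 180)
  height <- rnorm_trunc(n_subjects, sp$height_mean, sp$height_sd, 100, 230)
  n_male <- round(n_subjects * sp$male_frac)
  sex <- rep(c("M", "F"), c(n_male, n_subjects - n_male))
  pep <- rnorm_trunc(n_subjects, 0.08, k * 0.008, 0.05, 0.12)
  r_off <- rnorm(n_subjects, 127, k * 3)
  slope_s <- rnorm_trunc(n_subjects, 12, k * 0.6, 8, 16)
  slope_d <- rnorm_trunc(n_subjects, 8, k * 0.4, 5, 11)
  off_s <- rnorm(n_subjects, 60, k * 5)
  off_d <- rnorm(n_subjects, 40, k * 4)
  sv_gain <- rnorm_trunc(n_subjects, 20, k * 1.5, 10, 30)
  sv_int <- rnorm(n_subjects, 10, k * 4)
  sbp0 <- rnorm_trunc(n_subjects, 120, k * 9, 95, 165)
  hr0 <- rnorm_trunc(n_subjects, 74.3, k * 12.4, 47.8, 113.2)
  spo2_0 <- rnorm_trunc(n_subjects, 97.3, k * 0.8, 93, 99.5)
  sv0 <- rnorm_trunc(n_subjects, 70, k * 13, 35, 130)
  lapply(seq_len(n_subjects), function(i) {
    subject_profile(
      subject_id = sprintf("%s%03d", id_prefix, i),
      age = age[i], height = height[i], weight = weight[i], sex = sex[i],
      pep = pep[i], r_curve_offset = r_off[i],
      bp_slope_s = slope_s[i], bp_offset_s = off_s[i],
      bp_slope_d = slope_d[i], bp_offset_d = off_d[i],
      sv_gain = sv_gain[i], sv_intercept = sv_int[i],
      baseline = list(sbp = sbp0[i], hr = hr0[i], spo2 = spo2_0[i],
                      sv = sv0[i])
    )
  })
}

#' Construct a set of ground-truth vitals
#'
#' @param sbp,dbp systolic/diastolic pressure, mm Hg (sbp > dbp).
#' @param sv stroke volume, mL.
#' @param spo2 peripheral oxygen saturation, percent (0 < spo2 <= 100).
#' @param hr heart rate, bpm, within [30, 220].
#' @param hrv_sd SD of the RR-interval jitter, s.
#' @return an object of class `true_vitals`.
#' @export
true_vitals <- function(sbp, dbp, sv, spo2, hr, hrv_sd = 0.02) {
  if (!(sbp > dbp)) stop("sbp must exceed dbp")
  if (!(spo2 > 0 && spo2 <= 100)) stop("spo2 must be in (0, 100]")
  if (!(hr >= 30 && hr <= 220)) stop("hr must be within [30, 220] bpm")
  if (hrv_sd < 0) stop("hrv_sd must be >= 0")
  structure(list(sbp = sbp, dbp = dbp, sv = sv, spo2 = spo2,
                 hr = hr, hrv_sd = hrv_sd), class = "true_vitals")
}

#' Sample one session's true vitals for a subject
#'
#' Session vitals drift around the subject's baseline: systolic pressure
#' sets the transit time through the subject's ground-truth PWV model and
#' diastolic pressure follows the subject's diastolic map at that PWV plus
#' a small independent deviation (the unexplained within-subject variance).
#'
#' @param subject a [subject_profile()] with a `baseline` list.
#' @param seed integer seed.
#' @param sbp_sd,dbp_dev_sd,spo2_sd,hr_sd,sv_sd session-to-session SDs.
#' @return a [true_vitals()] object.
#' @export
sample_session_vitals <- function(subject, seed,
                                  sbp_sd = 7, dbp_dev_sd = 1.5,
                                  spo2_sd = 0.7, hr_sd = 3, sv_sd = 3) {
  b <- subject$baseline
  if (is.null(b)) stop("subject has no baseline vitals")
  set.seed(as.integer(seed))
  sbp <- rnorm_trunc(1, b$sbp, sbp_sd, 90, 185)
  pwv <- (sbp - subject$bp_offset_s) / subject$bp_slope_s
  dbp <- subject$bp_slope_d * pwv + subject$bp_offset_d +
    rnorm(1, 0, dbp_dev_sd)
  dbp <- min(dbp, sbp - 12)
  true_vitals(
    sbp = sbp, dbp = dbp,
    sv = rnorm_trunc(1, b$sv, sv_sd, 20, 160),
    spo2 = min(100, rnorm_trunc(1, b$spo2, spo2_sd, 85, 100.5)),
    hr = rnorm_trunc(1, b$hr, hr_sd, 40, 190)
  )
}

#' Per-channel noise specification for the generator
#'
#' @param ecg_sd,bcg_sd,ppg_sd additive white-noise SDs (mV, N, a.u.).
#' @param wander_ecg,wander_bcg,wander_ppg baseline-wander amplitudes.
#' @param wander_freq fundamental wander frequency, Hz.
#' @return a list of class `noise_spec`.
#' @export
noise_spec <- function(ecg_sd = 0.02, bcg_sd = 0.05, ppg_sd = 0.003,
                       wander_ecg = 0.05, wander_bcg = 0.2,
                       wander_ppg = 0.005, wander_freq = 0.15) {
  if (any(c(ecg_sd, bcg_sd, ppg_sd, wander_ecg, wander_bcg, wander_ppg) < 0))
    stop("noise SDs and wander amplitudes must be >= 0")
  structure(list(ecg_sd = ecg_sd, bcg_sd = bcg_sd, ppg_sd = ppg_sd,
                 wander_ecg = wander_ecg, wander_bcg = wander_bcg,
                 wander_ppg = wander_ppg, wander_freq = wander_freq),
            class = "noise_spec")
}

#' Zero-noise specification (clean signals)
#' @return a [noise_spec()] with all amplitudes zero.
#' @export
noise_none <- function() noise_spec(0, 0, 0, 0, 0, 0)

baseline_wander <- function(n, fs, amp, f0) {
  if (amp == 0) return(numeric(n))
  t <- (seq_len(n) - 1) / fs
  ph <- runif(2, 0, 2 * pi)
  amp * (sin(2 * pi * f0 * t + ph[1]) + 0.5 * sin(2 * pi * 1.7 * f0 * t + ph[2]))
}

new_recording <- function(fs, ecg, bcg, ppg_red, ppg_ir, duration,
                          subject_id, annotations = NULL, truth = NULL) {
  n <- round(fs * duration)
  lens <- c(length(ecg), length(bcg), length(ppg_red), length(ppg_ir))
  stopifnot(fs > 0, all(lens == n))
  if (!is.null(annotations) && nrow(annotations) > 0) {
    stopifnot(all(annotations$time_s >= 0 & annotations$time_s <= duration))
  }
  structure(list(fs = fs, duration = duration, subject_id = subject_id,
                 ecg = ecg, bcg = bcg, ppg_red = ppg_red, ppg_ir = ppg_ir,
                 annotations = annotations, truth = truth),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  n_ann <- if (is.null(x$annotations)) 0L else nrow(x$annotations)
  cat(sprintf(
    "<recording %s: %.0f s @ %g Hz, channels ecg/bcg/ppg_red/ppg_ir, %d annotations>\n",
    x$subject_id, x$duration, x$fs, n_ann))
  invisible(x)
}

annotation_times <- function(recording, event) {
  ann <- recording$annotations
  if (is.null(ann)) return(numeric(0))
  ann$time_s[ann$event_type == event]
}

#' Generate a coupled ECG/BCG/PPG recording encoding known vitals
#'
#' The forward model places an ECG beat at each R time (RR = 60/hr plus
#' Gaussian jitter of SD `hrv_sd`, snapped to the sample grid); a BCG
#' complex whose J wave falls at R + PEP and whose J-K amplitude equals
#' (sv - sv_intercept)/sv_gain; and a PPG pulse on each wavelength whose
#' intersecting-tangent foot falls at J + PTT, where PTT =
#' aortic_length/PWV and PWV = (sbp - bp_offset_s)/bp_slope_s.  The red and
#' infrared AC/DC ratios are set so the ratio-of-ratios R satisfies
#' spo2 = slope_pop * R + r_curve_offset.  Channel noise and baseline
#' wander are added per `noise`; annotations carry every true event time.
#'
#' @param subject a [subject_profile()].
#' @param vitals a [true_vitals()].
#' @param duration recording length, s (>= 10).
#' @param fs sampling rate, Hz (>= 100).
#' @param noise a [noise_spec()].
#' @param seed integer seed; identical inputs give identical recordings.
#' @param spo2_slope population R-curve slope, % per unit R (negative).
#' @param dc_red,dc_ir DC optical levels, a.u.
#' @param perfusion_ir infrared AC/DC ratio (the perfusion index).
#' @return a `recording` with `$annotations` (event_type, time_s, label)
#'   and `$truth` (closed-form ptt, pwv, r_value, jk_amplitude, ac/dc per
#'   wavelength, the vitals and the subject).
#' @export
generate_recording <- function(subject, vitals, duration = 60, fs = 1000,
                               noise = noise_spec(), seed = 1L,
                               spo2_slope = SPO2_SLOPE_DEFAULT,
                               dc_red = 1.2, dc_ir = 1.0,
                               perfusion_ir = 0.02) {
  stopifnot(inherits(subject, "subject_profile"), inherits(vitals, "true_vitals"))
  if (duration < 10) stop("duration must be >= 10 s")
  if (fs < 100) stop("fs must be >= 100 Hz")
  pwv <- (vitals$sbp - subject$bp_offset_s) / subject$bp_slope_s
  if (!is.finite(pwv) || pwv <= 0)
    stop(sprintf("non-positive PWV (%.2f m/s) implied by sbp=%.1f and the subject BP model",
                 pwv, vitals$sbp))
  ptt <- subject$aortic_length / pwv
  if (ptt <= 0) stop("non-positive PTT implied by parameters")
  if (subject$pep + ptt > 0.45)
    stop(sprintf("PEP + PTT = %.3f s too long for the beat window", subject$pep + ptt))
  jk <- (vitals$sv - subject$sv_intercept) / subject$sv_gain
  if (jk <= 0)
    stop("non-positive BCG J-K amplitude implied by sv and the subject SV model")
  r_value <- (vitals$spo2 - subject$r_curve_offset) / spo2_slope
  if (r_value <= 0)
    stop("non-positive R-value implied by spo2 and r_curve_offset")

  set.seed(as.integer(seed))
  n <- round(fs * duration)
  rr0 <- 60 / vitals$hr
  n_max <- ceiling(duration / rr0) + 10L
  rr <- rr0 + rnorm(n_max, 0, vitals$hrv_sd)
  rr <- round(pmax(rr, 0.4 * rr0) * fs) / fs     # snap RRs to the sample grid
  r_times <- round(0.5 * fs) / fs + cumsum(c(0, rr))
  r_times <- r_times[r_times < duration - 1.0]

  bcg_char <- characterize_bcg_template(fs)
  ppg_char <- characterize_ppg_template(fs)
  j_times <- r_times + subject$pep
  foot_times <- j_times + ptt
  ppg_onsets <- foot_times - ppg_char$foot_offset

  ecg <- bcg <- numeric(n)
  ppg_pulse <- numeric(n)
  amp_bcg <- jk / bcg_char$jk_unit
  for (k in seq_along(r_times)) {
    ecg <- add_template(ecg, fs, r_times[k], 1, ecg_beat_template, 0.32, 0.55)
    bcg <- add_template(bcg, fs, j_times[k], amp_bcg, bcg_beat_template,
                        bcg_char$half_support, bcg_char$half_support)
    ppg_pulse <- add_template(ppg_pulse, fs, ppg_onsets[k], 1,
                              ppg_beat_template, 0, ppg_char$support)
  }
  ac_ir <- perfusion_ir * dc_ir
  ac_red <- r_value * perfusion_ir * dc_red
  ppg_red <- dc_red + ac_red * ppg_pulse
  ppg_ir <- dc_ir + ac_ir * ppg_pulse

  ecg <- ecg + rnorm(n, 0, noise$ecg_sd) +
    baseline_wander(n, fs, noise$wander_ecg, noise$wander_freq)
  bcg <- bcg + rnorm(n, 0, noise$bcg_sd) +
    baseline_wander(n, fs, noise$wander_bcg, noise$wander_freq)
  ppg_red <- ppg_red + rnorm(n, 0, noise$ppg_sd) +
    baseline_wander(n, fs, noise$wander_ppg, noise$wander_freq)
  ppg_ir <- ppg_ir + rnorm(n, 0, noise$ppg_sd) +
    baseline_wander(n, fs, noise$wander_ppg, noise$wander_freq)

  ann <- rbind(
    data.frame(event_type = "r_peak", time_s = r_times, label = "true"),
    data.frame(event_type = "j_wave", time_s = j_times, label = "true"),
    data.frame(event_type = "ppg_foot", time_s = foot_times, label = "true")
  )
  truth <- list(
    ptt = ptt, pwv = pwv, r_value = r_value, jk_amplitude = jk,
    ac_red = ac_red, dc_red = dc_red, ac_ir = ac_ir, dc_ir = dc_ir,
    vitals = vitals, subject = subject
  )
  new_recording(fs, ecg, bcg, ppg_red, ppg_ir, duration,
                subject$subject_id, ann, truth)
}

#' Inject artifacts into a recording
#'
#' Artifact types: `motion_burst` adds high-amplitude broadband noise to
#' the BCG and both PPG channels; `ectopic_beat` inserts a premature beat
#' (ECG QRS plus attenuated BCG/PPG complexes) at the onset time,
#' shortening one RR interval; `dropout` zeroes a window on all channels.
#' Annotations gain rows labelled with the artifact type.
#'
#' @param recording a `recording`.
#' @param artifact_spec a data.frame with columns `type`, `onset`,
#'   `duration`, `magnitude` (magnitude is a scale factor relative to the
#'   channel's nominal amplitude; for `ectopic_beat` it scales the inserted
#'   beat, default 0.8).
#' @param seed integer seed for the broadband noise.
#' @return the modified `recording`.
#' @export
inject_artifacts <- function(recording, artifact_spec, seed = 1L) {
  stopifnot(inherits(recording, "recording"))
  if (is.null(artifact_spec) || nrow(artifact_spec) == 0) return(recording)
  fs <- recording$fs
  set.seed(as.integer(seed))
  for (k in seq_len(nrow(artifact_spec))) {
    a <- artifact_spec[k, ]
    if (a$onset < 0 || a$onset + a$duration > recording$duration)
      stop("artifact window outside the recording")
    i0 <- max(1L, round(a$onset * fs) + 1L)
    i1 <- min(length(recording$bcg), round((a$onset + a$duration) * fs))
    idx <- i0:i1
    if (a$type == "motion_burst") {
      recording$bcg[idx] <- recording$bcg[idx] + rnorm(length(idx), 0, a$magnitude * 3)
      recording$ppg_red[idx] <- recording$ppg_red[idx] + rnorm(length(idx), 0, a$magnitude * 0.05)
      recording$ppg_ir[idx] <- recording$ppg_ir[idx] + rnorm(length(idx), 0, a$magnitude * 0.05)
    } else if (a$type == "dropout") {
      for (ch in c("ecg", "bcg", "ppg_red", "ppg_ir"))
        recording[[ch]][idx] <- 0
    } else if (a$type == "ectopic_beat") {
      mag <- if (is.na(a$magnitude)) 0.8 else a$magnitude
      t_ect <- round(a$onset * fs) / fs
      recording$ecg <- add_template(recording$ecg, fs, t_ect, mag,
                                    ecg_beat_template, 0.32, 0.55)
      bcg_char <- characterize_bcg_template(fs)
      tr <- recording$truth
      amp <- if (!is.null(tr)) 0.6 * mag * tr$jk_amplitude / bcg_char$jk_unit else 0.5
      recording$bcg <- add_template(recording$bcg, fs, t_ect + 0.08, amp,
                                    bcg_beat_template, bcg_char$half_support,
                                    bcg_char$half_support)
      recording$annotations <- rbind(
        recording$annotations,
        data.frame(event_type = "r_peak", time_s = t_ect, label = "ectopic_beat"))
    } else {
      stop(sprintf("unknown artifact type '%s'", a$type))
    }
    if (a$type != "ectopic_beat") {
      recording$annotations <- rbind(
        recording$annotations,
        data.frame(event_type = "artifact", time_s = a$onset, label = a$type))
    }
  }
  recording$annotations <- recording$annotations[order(recording$annotations$time_s), ]
  recording
}
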
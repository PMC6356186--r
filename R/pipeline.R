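# End-to-end orchestration: configuration, per-recording processing,
# cohort simulation, and the synthetic validation study.

#' Pipeline configuration
#'
#' All tunable processing parameters in one serializable object.
#'
#' @param fs sampling rate, Hz.
#' @param ecg_band,bcg_band,ppg_band per-channel band-pass edges, Hz
#'   (zero-phase).  The ECG band feeds R detection; the BCG band is applied
#'   before ensembling; the PPG band is kept for optional pre-filtering but
#'   PPG is ensembled raw by default so the DC level survives.
#' @param rr_tolerance fractional RR deviation for abnormal-beat removal.
#' @param min_beats,min_span,max_motion recording-level quality thresholds.
#' @param j_window BCG J search window, s after R.
#' @param ensemble_window `c(before, after)` s around R.
#' @param bp_slopes population BP slopes `c(systolic, diastolic)`,
#'   mm Hg per unit predictor.
#' @param bp_predictor `"pwv"` or `"inverse_ptt"`.
#' @param spo2_slope population R-curve slope, % per unit R.
#' @param aortic_coef aortic length per height (m/m).
#' @param ptt_wavelength PPG channel providing the peripheral timing point.
#' @param seed default seed for simulation commands.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(fs = 1000,
                            ecg_band = c(0.5, 40), bcg_band = c(0.5, 20),
                            ppg_band = c(0.3, 10),
                            rr_tolerance = 0.20,
                            min_beats = 20, min_span = 30, max_motion = 0.2,
                            j_window = c(0.05, 0.40),
                            ensemble_window = c(0.2, 0.8),
                            bp_slopes = c(12, 8),
                            bp_predictor = c("pwv", "inverse_ptt"),
                            spo2_slope = SPO2_SLOPE_DEFAULT,
                            aortic_coef = 0.285,
                            ptt_wavelength = c("ppg_ir", "ppg_red"),
                            seed = 1L) {
  bp_predictor <- match.arg(bp_predictor)
  ptt_wavelength <- match.arg(ptt_wavelength)
  stopifnot(fs >= 100, rr_tolerance > 0, rr_tolerance < 1,
            min_beats >= 1, min_span > 0, max_motion >= 0, max_motion <= 1,
            spo2_slope < 0, aortic_coef > 0)
  structure(list(fs = fs, ecg_band = ecg_band, bcg_band = bcg_band,
                 ppg_band = ppg_band, rr_tolerance = rr_tolerance,
                 min_beats = min_beats, min_span = min_span,
                 max_motion = max_motion, j_window = j_window,
                 ensemble_window = ensemble_window, bp_slopes = bp_slopes,
                 bp_predictor = bp_predictor, spo2_slope = spo2_slope,
                 aortic_coef = aortic_coef, ptt_wavelength = ptt_wavelength,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (plain-text key-value)
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return the path (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  writeLines(vapply(names(config), function(f)
    sprintf("%s: %s", f, paste(format(config[[f]], digits = 15), collapse = ",")),
    character(1)), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  kv <- read_keyvalue(path)
  num <- function(f) as.numeric(strsplit(kv[[f]], ",")[[1]])
  pipeline_config(
    fs = num("fs"), ecg_band = num("ecg_band"), bcg_band = num("bcg_band"),
    ppg_band = num("ppg_band"), rr_tolerance = num("rr_tolerance"),
    min_beats = num("min_beats"), min_span = num("min_span"),
    max_motion = num("max_motion"), j_window = num("j_window"),
    ensemble_window = num("ensemble_window"), bp_slopes = num("bp_slopes"),
    bp_predictor = trimws(kv$bp_predictor), spo2_slope = num("spo2_slope"),
    aortic_coef = num("aortic_coef"),
    ptt_wavelength = trimws(kv$ptt_wavelength), seed = num("seed")
  )
}

#' Extract quality-gated fiducial features from a recording
#'
#' Runs R detection, abnormal-beat removal, the recording-level quality
#' check, ensemble averaging and fiducial extraction.  Rejected recordings
#' return the quality report and `NULL` features.
#'
#' @param recording a `recording`.
#' @param config a [pipeline_config()].
#' @return a list `(quality, beats, features)`; `features` holds `j_time`,
#'   `jk_amplitude`, `foot_time` (per the configured PTT wavelength),
#'   `ac_red`, `dc_red`, `ac_ir`, `dc_ir`, `r_value`, `hr`, `n_beats`,
#'   `flags`.
#' @export
extract_features <- function(recording, config = pipeline_config()) {
  stopifnot(inherits(recording, "recording"))
  beats <- detect_r_peaks(recording$ecg, recording$fs, band = config$ecg_band)
  if (length(beats$r_times) >= 3)
    beats <- filter_abnormal_beats(beats, tolerance = config$rr_tolerance)
  else {
    beats$accepted <- rep(FALSE, length(beats$r_times))
    beats$rejection_reason <- rep("too_few", length(beats$r_times))
  }
  quality <- assess_recording(recording, beats, min_beats = config$min_beats,
                              min_span = config$min_span,
                              max_motion = config$max_motion)
  if (!quality$recording_accepted)
    return(list(quality = quality, beats = beats, features = NULL))
  flags <- character(0)
  ens_bcg <- ensemble_average(recording, beats, "bcg",
                              window = config$ensemble_window,
                              band = config$bcg_band)
  fid <- locate_bcg_fiducials(ens_bcg, search_window = config$j_window)
  flags <- c(flags, fid$flags)
  ens_red <- ensemble_average(recording, beats, "ppg_red",
                              window = config$ensemble_window)
  ens_ir <- ensemble_average(recording, beats, "ppg_ir",
                             window = config$ensemble_window)
  acdc_red <- measure_ppg_ac_dc(ens_red)
  acdc_ir <- measure_ppg_ac_dc(ens_ir)
  flags <- c(flags, acdc_red$flags, acdc_ir$flags)
  ens_ptt <- if (config$ptt_wavelength == "ppg_ir") ens_ir else ens_red
  foot <- locate_ppg_foot(ens_ptt)
  if (is.na(foot)) flags <- c(flags, attr(foot, "flag"))
  r_value <- if (length(c(acdc_red$flags, acdc_ir$flags)) == 0)
    compute_r_value(acdc_red$ac, acdc_red$dc, acdc_ir$ac, acdc_ir$dc)
  else NA_real_
  rr_acc <- diff(beats$r_times[beats$accepted])
  hr <- 60 / stats::median(rr_acc)
  list(quality = quality, beats = beats, features = list(
    j_time = fid$bcg_j$time, jk_amplitude = fid$jk_amplitude,
    foot_time = as.numeric(foot),
    ac_red = acdc_red$ac, dc_red = acdc_red$dc,
    ac_ir = acdc_ir$ac, dc_ir = acdc_ir$dc,
    r_value = r_value, hr = hr, n_beats = quality$n_beats_accepted,
    flags = flags
  ))
}

#' Calibrate a subject from a single session
#'
#' Completes a [calibration_model()] from one recording plus its
#' gold-standard references, exactly as a single calibration session:
#' per-subject BP offsets at fixed population slopes, and the subject's
#' R-curve offset at the fixed population slope.
#'
#' @param recording the calibration-session `recording`.
#' @param gold a list or [true_vitals()] with `sbp`, `dbp`, `spo2`.
#' @param height subject height, cm (for the aortic length estimate).
#' @param config a [pipeline_config()].
#' @param sv_coef optional `c(sv_intercept, sv_gain)` population SV
#'   coefficients to embed.
#' @return a `calibration_model`, or `NULL` when the recording fails the
#'   quality gate.
#' @export
calibrate_subject <- function(recording, gold, height,
                              config = pipeline_config(), sv_coef = NULL) {
  ex <- extract_features(recording, config)
  if (is.null(ex$features)) return(NULL)
  f <- ex$features
  L <- estimate_aortic_length(height, coef = config$aortic_coef)
  model <- calibration_model(subject_id = recording$subject_id,
                             aortic_length = L,
                             spo2_slope = config$spo2_slope,
                             bp_predictor = config$bp_predictor)
  tp <- compute_ptt_pwv(f$j_time, f$foot_time, L)
  if (length(tp$flags)) stop("calibration session yielded a non-positive PTT")
  model <- calibrate_bp(
    data.frame(pwv = tp$pwv, cuff_sbp = gold$sbp, cuff_dbp = gold$dbp),
    population_slopes = config$bp_slopes, model = model)
  model <- calibrate_spo2(f$r_value, gold$spo2, slope = config$spo2_slope,
                          model = model)
  if (!is.null(sv_coef)) {
    model$sv_intercept <- sv_coef[[1]]
    model$sv_gain <- sv_coef[[2]]
  }
  model
}

#' Process one recording into a vitals estimate
#'
#' Full chain: quality gate, beats, ensembles, fiducials, calibrated
#' estimation.  Rejected recordings yield the quality report and no
#' estimate row.
#'
#' @param recording a `recording`, or a file stem readable by
#'   [read_recording()].
#' @param calibration a `calibration_model`, or a path readable by
#'   [read_calibration()].
#' @param config a [pipeline_config()].
#' @param recording_id identifier echoed in the estimate row.
#' @return a list `(estimate, quality)`; `estimate` is a one-row
#'   data.frame (recording_id, subject_id, ptt, pwv, r_value, sbp, dbp,
#'   spo2, sv, co, hr, n_beats, flags) or `NULL`.
#' @export
process_recording <- function(recording, calibration,
                              config = pipeline_config(),
                              recording_id = NA_character_) {
  if (is.character(recording)) recording <- read_recording(recording)
  if (is.character(calibration)) calibration <- read_calibration(calibration)
  stopifnot(inherits(recording, "recording"),
            inherits(calibration, "calibration_model"))
  if (!is.na(calibration$subject_id) &&
      !identical(calibration$subject_id, recording$subject_id))
    stop(sprintf("calibration is for subject '%s' but the recording is '%s'",
                 calibration$subject_id, recording$subject_id))
  ex <- extract_features(recording, config)
  if (is.null(ex$features)) return(list(estimate = NULL, quality = ex$quality))
  f <- ex$features
  tp <- compute_ptt_pwv(f$j_time, f$foot_time, calibration$aortic_length)
  flags <- c(f$flags, tp$flags)
  if (is.na(tp$pwv)) {
    bp <- list(sbp = NA_real_, dbp = NA_real_, flags = character(0))
  } else {
    bp <- estimate_bp(calibration, tp$pwv)
    flags <- c(flags, bp$flags)
  }
  spo2 <- if (is.na(f$r_value)) NA_real_ else estimate_spo2(calibration, f$r_value)
  sv <- estimate_sv(f$jk_amplitude, calibration)
  flags <- c(flags, sv$flags)
  co <- if (is.na(sv$sv)) NA_real_ else compute_co(sv$sv, f$hr)
  est <- data.frame(
    recording_id = recording_id, subject_id = recording$subject_id,
    ptt = tp$ptt, pwv = tp$pwv, r_value = f$r_value,
    sbp = bp$sbp, dbp = bp$dbp, spo2 = spo2, sv = sv$sv, co = co,
    hr = f$hr, n_beats = f$n_beats,
    flags = paste(unique(flags), collapse = ";"),
    stringsAsFactors = FALSE
  )
  list(estimate = est, quality = ex$quality)
}

study_seed <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) * 48271 + i * 1299709 + j * 104729) %% 2147483647)
}

#' Simulate a multi-session validation study
#'
#' Generates a cohort and, for each subject, `n_sessions` recordings with
#' session-to-session drifting true vitals.  Session 1 is the designated
#' calibration session.
#'
#' @param n_subjects,n_sessions study size.
#' @param cohort a [cohort_spec()] preset name.
#' @param duration,fs per-recording length and sampling rate.
#' @param noise a [noise_spec()].
#' @param seed integer master seed; every random draw derives from it.
#' @return a list of class `study`: `subjects`, `sessions` (per subject, a
#'   list of `(recording, gold)`), and the generation parameters.
#' @export
simulate_study <- function(n_subjects = 12, n_sessions = 10,
                           cohort = "dbp", duration = 60, fs = 1000,
                           noise = noise_spec(), seed = 1L) {
  subjects <- generate_cohort(n_subjects, cohort_spec(cohort),
                              seed = study_seed(seed, 0L))
  sessions <- lapply(seq_len(n_subjects), function(i) {
    lapply(seq_len(n_sessions), function(j) {
      vit <- sample_session_vitals(subjects[[i]], seed = study_seed(seed, i, j))
      rec <- generate_recording(subjects[[i]], vit, duration = duration,
                                fs = fs, noise = noise,
                                seed = study_seed(seed, i, j + 1000L))
      list(recording = rec, gold = vit)
    })
  })
  structure(list(subjects = subjects, sessions = sessions,
                 n_subjects = n_subjects, n_sessions = n_sessions,
                 duration = duration, fs = fs, seed = seed),
            class = "study")
}

#' @export
print.study <- function(x, ...) {
  cat(sprintf("<study: %d subjects x %d sessions, %.0f s @ %g Hz, seed %d>\n",
              x$n_subjects, x$n_sessions, x$duration, x$fs, x$seed))
  invisible(x)
}

#' Write / read a simulated study as a directory of plain-text files
#'
#' Layout: `subjects.csv` plus, per subject and session,
#' `<id>_s<k>.csv/.meta/.events.csv` ([write_recording()] format) and
#' `<id>_s<k>.gold` (key-value ground-truth vitals).
#'
#' @param study a `study`.
#' @param dir directory (created if needed).
#' @return the directory (write) or a `study` (read).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subj <- do.call(rbind, lapply(study$subjects, function(s)
    data.frame(subject_id = s$subject_id, age = s$age, sex = s$sex,
               height = s$height, weight = s$weight, bmi = s$bmi)))
  utils::write.csv(subj, file.path(dir, "subjects.csv"), row.names = FALSE)
  for (i in seq_along(study$subjects)) {
    id <- study$subjects[[i]]$subject_id
    for (j in seq_along(study$sessions[[i]])) {
      ses <- study$sessions[[i]][[j]]
      stem <- file.path(dir, sprintf("%s_s%02d", id, j))
      write_recording(ses$recording, stem)
      g <- ses$gold
      writeLines(sprintf("%s: %.10g", c("sbp", "dbp", "sv", "spo2", "hr"),
                         c(g$sbp, g$dbp, g$sv, g$spo2, g$hr)),
                 paste0(stem, ".gold"))
    }
  }
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  subj <- utils::read.csv(file.path(dir, "subjects.csv"),
                          colClasses = c(subject_id = "character"))
  subjects <- lapply(seq_len(nrow(subj)), function(i)
    subject_profile(subj$subject_id[i], age = subj$age[i],
                    height = subj$height[i], weight = subj$weight[i],
                    sex = subj$sex[i]))
  sessions <- lapply(subjects, function(s) {
    stems <- sort(sub("\\.meta$", "",
                      list.files(dir, pattern = paste0("^", s$subject_id,
                                                       "_s[0-9]+\\.meta$"),
                                 full.names = TRUE)))
    if (length(stems) < 2) stop(sprintf(
      "subject %s has fewer than 2 sessions", s$subject_id))
    lapply(stems, function(st) {
      kv <- read_keyvalue(paste0(st, ".gold"))
      gold <- lapply(kv, as.numeric)
      list(recording = read_recording(st), gold = gold)
    })
  })
  structure(list(subjects = subjects, sessions = sessions,
                 n_subjects = length(subjects),
                 n_sessions = length(sessions[[1]]),
                 duration = sessions[[1]][[1]]$recording$duration,
                 fs = sessions[[1]][[1]]$recording$fs, seed = NA_integer_),
            class = "study")
}

#' Fit the population stroke-volume model on a training study
#'
#' Processes every recording of the training study and regresses the gold
#' stroke volume on the measured ensemble J-K amplitude.
#'
#' @param study a `study`.
#' @param config a [pipeline_config()].
#' @return `c(sv_intercept, sv_gain)`.
#' @export
fit_sv_model_on_study <- function(study, config = pipeline_config()) {
  jk <- sv <- numeric(0)
  for (i in seq_along(study$subjects)) {
    for (ses in study$sessions[[i]]) {
      ex <- extract_features(ses$recording, config)
      if (is.null(ex$features) || !is.finite(ex$features$jk_amplitude)) next
      jk <- c(jk, ex$features$jk_amplitude)
      sv <- c(sv, ses$gold$sv)
    }
  }
  fit_sv_model(jk, sv)
}

#' Evaluate stroke-volume estimation on a study with a population model
#'
#' Stroke volume needs no per-subject calibration: the population
#' coefficients (fit on a disjoint training study) map each recording's
#' ensemble J-K amplitude to SV.  Every session of every subject is
#' evaluated against its gold-standard SV.
#'
#' @param study a `study` (typically one session per subject).
#' @param sv_coef `c(sv_intercept, sv_gain)`, or `NULL` to fit on
#'   `sv_train`.
#' @param sv_train optional training `study`.
#' @param config a [pipeline_config()].
#' @return a list: `ba` (a `bland_altman_result` of seat vs gold SV),
#'   `strata` (BMI-stratified errors), `sv_coef`, `n_rejected`.
#' @export
evaluate_sv_study <- function(study, sv_coef = NULL, sv_train = NULL,
                              config = pipeline_config()) {
  if (is.null(sv_coef)) {
    if (is.null(sv_train)) stop("need sv_coef or a training study")
    sv_coef <- fit_sv_model_on_study(sv_train, config)
  }
  model <- calibration_model(sv_intercept = sv_coef[[1]], sv_gain = sv_coef[[2]])
  est <- gold <- bmi <- numeric(0); n_rejected <- 0L
  for (i in seq_along(study$subjects)) {
    for (ses in study$sessions[[i]]) {
      ex <- extract_features(ses$recording, config)
      if (is.null(ex$features) || !is.finite(ex$features$jk_amplitude)) {
        n_rejected <- n_rejected + 1L; next
      }
      est <- c(est, estimate_sv(ex$features$jk_amplitude, model)$sv)
      gold <- c(gold, ses$gold$sv)
      bmi <- c(bmi, study$subjects[[i]]$bmi)
    }
  }
  ba <- bland_altman(est, gold)
  list(ba = ba,
       strata = stratify(data.frame(difference = est - gold, bmi = bmi)),
       sv_coef = sv_coef, n_rejected = n_rejected)
}

#' Run the synthetic device-validation study
#'
#' Calibrates each subject from their first session (BP offsets and
#' R-curve offset), processes the remaining sessions, and compares the
#' estimates with the per-session gold-standard values: Bland-Altman
#' statistics, AAMI/ISO compliance verdicts and BMI stratification, per
#' measure.  Stroke volume is evaluated when population SV coefficients
#' are supplied (or a training study to fit them on).
#'
#' @param study a `study` or a directory written by [write_study()].
#' @param config a [pipeline_config()].
#' @param sv_coef optional `c(sv_intercept, sv_gain)`.
#' @param sv_train optional training `study` passed to
#'   [fit_sv_model_on_study()].
#' @return a list of class `validation_report`: per-measure
#'   `bland_altman_result`s, `compliance` verdicts, `strata`, the pooled
#'   estimate/gold table, counts of rejected recordings, and the config.
#' @export
run_validation_study <- function(study, config = pipeline_config(),
                                 sv_coef = NULL, sv_train = NULL) {
  if (is.character(study)) study <- read_study(study)
  stopifnot(inherits(study, "study"))
  if (is.null(sv_coef) && !is.null(sv_train))
    sv_coef <- fit_sv_model_on_study(sv_train, config)
  rows <- list(); n_rejected <- 0L; n_uncalibrated <- 0L
  for (i in seq_along(study$subjects)) {
    s <- study$subjects[[i]]
    ses <- study$sessions[[i]]
    if (length(ses) < 2) stop("fewer than 2 sessions per subject")
    model <- calibrate_subject(ses[[1]]$recording, ses[[1]]$gold, s$height,
                               config, sv_coef = sv_coef)
    if (is.null(model)) { n_uncalibrated <- n_uncalibrated + 1L; next }
    for (j in seq(2, length(ses))) {
      out <- process_recording(ses[[j]]$recording, model, config,
                               recording_id = sprintf("%s_s%02d", s$subject_id, j))
      if (is.null(out$estimate)) { n_rejected <- n_rejected + 1L; next }
      g <- ses[[j]]$gold
      rows[[length(rows) + 1L]] <- cbind(
        out$estimate,
        data.frame(gold_sbp = g$sbp, gold_dbp = g$dbp, gold_sv = g$sv,
                   gold_spo2 = g$spo2, gold_hr = g$hr, bmi = s$bmi))
    }
  }
  if (!length(rows)) stop("no recordings survived the quality gate")
  tab <- do.call(rbind, rows)
  ba_dbp <- bland_altman(tab$dbp, tab$gold_dbp)
  ba_sbp <- bland_altman(tab$sbp, tab$gold_sbp)
  ba_spo2 <- bland_altman(tab$spo2, tab$gold_spo2)
  ba_sv <- if (!is.null(sv_coef)) bland_altman(tab$sv, tab$gold_sv) else NULL
  report <- list(
    dbp = ba_dbp, sbp = ba_sbp, spo2 = ba_spo2, sv = ba_sv,
    compliance = list(
      aami_dbp = check_compliance(ba_dbp, "AAMI_BP"),
      aami_sbp = check_compliance(ba_sbp, "AAMI_BP"),
      iso_spo2 = check_compliance(ba_spo2, "ISO_SPO2")
    ),
    strata = list(
      dbp = stratify(data.frame(difference = tab$dbp - tab$gold_dbp, bmi = tab$bmi)),
      sbp = stratify(data.frame(difference = tab$sbp - tab$gold_sbp, bmi = tab$bmi))
    ),
    estimates = tab, n_rejected = n_rejected,
    n_uncalibrated = n_uncalibrated, config = config
  )
  class(report) <- "validation_report"
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Synthetic device-validation study\n")
  cat(sprintf("  DBP : bias %6.2f (SD %5.2f) mm Hg, n=%d  [AAMI %s]\n",
              x$dbp$bias, x$dbp$sd, x$dbp$n,
              if (x$compliance$aami_dbp$pass) "pass" else "FAIL"))
  cat(sprintf("  SBP : bias %6.2f (SD %5.2f) mm Hg, n=%d  [AAMI %s]\n",
              x$sbp$bias, x$sbp$sd, x$sbp$n,
              if (x$compliance$aami_sbp$pass) "pass" else "FAIL"))
  cat(sprintf("  SpO2: A_RMS %.2f %%, n=%d            [ISO %s]\n",
              x$spo2$arms, x$spo2$n,
              if (x$compliance$iso_spo2$pass) "pass" else "FAIL"))
  if (!is.null(x$sv))
    cat(sprintf("  SV  : bias %6.2f mL, LoA %.1f mL, n=%d\n",
                x$sv$bias, x$sv$loa_halfwidth, x$sv$n))
  if (x$n_rejected) cat(sprintf("  %d recordings rejected by the quality gate\n",
                                x$n_rejected))
  invisible(x)
}

#' Write a validation report to CSV + text
#'
#' @param report a `validation_report`.
#' @param stem output path stem; writes `<stem>_summary.csv`,
#'   `<stem>_estimates.csv`, `<stem>_config.txt`.
#' @export
write_validation_report <- function(report, stem) {
  stopifnot(inherits(report, "validation_report"))
  ba_row <- function(name, ba, verdict = NULL) data.frame(
    measure = name, n = ba$n, bias = ba$bias, sd = ba$sd,
    loa_halfwidth = ba$loa_halfwidth, arms = ba$arms,
    pass = if (is.null(verdict)) NA else verdict$pass)
  summ <- rbind(
    ba_row("dbp", report$dbp, report$compliance$aami_dbp),
    ba_row("sbp", report$sbp, report$compliance$aami_sbp),
    ba_row("spo2", report$spo2, report$compliance$iso_spo2),
    if (!is.null(report$sv)) ba_row("sv", report$sv))
  utils::write.csv(summ, paste0(stem, "_summary.csv"), row.names = FALSE)
  utils::write.csv(report$estimates, paste0(stem, "_estimates.csv"),
                   row.names = FALSE)
  write_pipeline_config(report$config, paste0(stem, "_config.txt"))
  invisible(stem)
}
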
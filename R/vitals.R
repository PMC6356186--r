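# Calibrated estimation of PTT/PWV, blood pressure, SpO2, stroke volume
# and cardiac output from fiducial features.

#' Estimate aortic length from standing height
#'
#' Linear anthropometric approximation: aortic length in metres equals a
#' fixed fraction of height.  The coefficient is configurable; the default
#' 0.285 places a 175 cm subject at ~0.50 m.
#'
#' @param height cm, within [100, 230].
#' @param coef m of aorta per m of height (> 0).
#' @return aortic length, m.
#' @export
estimate_aortic_length <- function(height, coef = 0.285) {
  if (any(height < 100 | height > 230)) stop("height outside [100, 230] cm")
  if (coef <= 0) stop("aortic length coefficient must be positive")
  coef * height / 100
}

#' Pulse transit time and pulse wave velocity
#'
#' Aortic PTT is the interval from the BCG ejection feature (J wave) to the
#' peripheral PPG foot; PWV is the aortic length divided by that time.
#' PEP is excluded by construction because the proximal point is the J
#' wave, not the ECG R peak.
#'
#' @param bcg_j_time,ppg_foot_time seconds relative to the R peak.
#' @param aortic_length m.
#' @return a list `(ptt, pwv, flags)`; a non-positive PTT yields `NA`
#'   values flagged `"nonpositive_ptt"`.
#' @export
compute_ptt_pwv <- function(bcg_j_time, ppg_foot_time, aortic_length) {
  stopifnot(aortic_length > 0)
  ptt <- ppg_foot_time - bcg_j_time
  if (!is.finite(ptt) || ptt <= 0)
    return(list(ptt = NA_real_, pwv = NA_real_, flags = "nonpositive_ptt"))
  list(ptt = ptt, pwv = aortic_length / ptt, flags = character(0))
}

#' Construct (or complete) a per-subject calibration model
#'
#' @param subject_id subject the model is calibrated for.
#' @param aortic_length m.
#' @param bp_slope_s,bp_slope_d population slopes, mm Hg per (m/s).
#' @param bp_offset_s,bp_offset_d per-subject offsets, mm Hg (NA until
#'   calibrated).
#' @param spo2_slope population R-curve slope, % per unit R (negative).
#' @param spo2_offset per-subject R-curve offset, % (NA until calibrated).
#' @param sv_intercept,sv_gain population stroke-volume coefficients
#'   (mL, mL per N); `sv_gain` must be positive.
#' @param bp_predictor `"pwv"` (default) or `"inverse_ptt"`: the predictor
#'   the BP linear model is expressed in.
#' @return an object of class `calibration_model`.
#' @export
calibration_model <- function(subject_id = NA_character_,
                              aortic_length = NA_real_,
                              bp_slope_s = 12, bp_slope_d = 8,
                              bp_offset_s = NA_real_, bp_offset_d = NA_real_,
                              spo2_slope = SPO2_SLOPE_DEFAULT,
                              spo2_offset = NA_real_,
                              sv_intercept = 10, sv_gain = 20,
                              bp_predictor = c("pwv", "inverse_ptt")) {
  bp_predictor <- match.arg(bp_predictor)
  if (!is.na(aortic_length) && aortic_length <= 0)
    stop("aortic_length must be positive")
  if (spo2_slope >= 0) stop("spo2_slope must be negative")
  if (sv_gain <= 0) stop("sv_gain must be positive")
  structure(list(subject_id = subject_id, aortic_length = aortic_length,
                 bp_slope_s = bp_slope_s, bp_slope_d = bp_slope_d,
                 bp_offset_s = bp_offset_s, bp_offset_d = bp_offset_d,
                 spo2_slope = spo2_slope, spo2_offset = spo2_offset,
                 sv_intercept = sv_intercept, sv_gain = sv_gain,
                 bp_predictor = bp_predictor),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model for %s>\n", x$subject_id))
  cat(sprintf("  BP (%s): sbp = %.2f*x + %s, dbp = %.2f*x + %s\n",
              x$bp_predictor, x$bp_slope_s, format(x$bp_offset_s),
              x$bp_slope_d, format(x$bp_offset_d)))
  cat(sprintf("  SpO2: %.1f*R + %s ; SV: %.1f + %.1f*JK ; L = %s m\n",
              x$spo2_slope, format(x$spo2_offset), x$sv_intercept,
              x$sv_gain, format(x$aortic_length)))
  invisible(x)
}

bp_predictor_value <- function(model, pwv) {
  switch(model$bp_predictor,
         pwv = pwv,
         inverse_ptt = pwv / model$aortic_length)
}

#' Single-session blood-pressure calibration
#'
#' Slopes are fixed at the population values; the per-subject offsets are
#' chosen so the model is exact at the calibration-session mean:
#' offset = mean(cuff) - slope * mean(predictor).
#'
#' @param calib_features data.frame with columns `pwv`, `cuff_sbp`,
#'   `cuff_dbp` (one row per calibration recording; >= 1 row).
#' @param population_slopes `c(s, d)` mm Hg per unit predictor.
#' @param model a [calibration_model()] to complete (carries
#'   `aortic_length` and `bp_predictor`).
#' @return the model with `bp_offset_s`/`bp_offset_d` filled in.
#' @export
calibrate_bp <- function(calib_features, population_slopes = c(12, 8),
                         model = calibration_model()) {
  if (is.null(calib_features) || nrow(calib_features) < 1)
    stop("empty calibration set")
  stopifnot(all(c("pwv", "cuff_sbp", "cuff_dbp") %in% names(calib_features)))
  model$bp_slope_s <- population_slopes[1]
  model$bp_slope_d <- population_slopes[2]
  x <- bp_predictor_value(model, calib_features$pwv)
  model$bp_offset_s <- mean(calib_features$cuff_sbp) - model$bp_slope_s * mean(x)
  model$bp_offset_d <- mean(calib_features$cuff_dbp) - model$bp_slope_d * mean(x)
  model
}

#' Estimate blood pressure from PWV through a calibrated model
#'
#' @param model a BP-calibrated [calibration_model()].
#' @param pwv m/s.
#' @return a list `(sbp, dbp, flags)`; `flags` contains
#'   `"sbp_not_above_dbp"` if the linear maps cross.
#' @export
estimate_bp <- function(model, pwv) {
  stopifnot(inherits(model, "calibration_model"))
  if (is.na(model$bp_offset_s) || is.na(model$bp_offset_d))
    stop("model is not BP-calibrated for a subject; no population-only BP")
  x <- bp_predictor_value(model, pwv)
  sbp <- model$bp_slope_s * x + model$bp_offset_s
  dbp <- model$bp_slope_d * x + model$bp_offset_d
  flags <- if (!(sbp > dbp)) "sbp_not_above_dbp" else character(0)
  list(sbp = sbp, dbp = dbp, flags = flags)
}

#' Ratio-of-ratios R-value from two-wavelength PPG amplitudes
#'
#' R = (AC_red/DC_red) / (AC_ir/DC_ir); invariant to per-wavelength gain.
#'
#' @param ac_red,dc_red,ac_ir,dc_ir amplitudes, a.u., all positive.
#' @return R, dimensionless.
#' @export
compute_r_value <- function(ac_red, dc_red, ac_ir, dc_ir) {
  if (any(c(ac_red, dc_red, ac_ir, dc_ir) <= 0))
    stop("all AC/DC inputs must be positive")
  (ac_red / dc_red) / (ac_ir / dc_ir)
}

#' Single-point SpO2 calibration (per-subject R-curve offset)
#'
#' The population slope is shared; the subject-specific offset is set so
#' the R-curve passes through the calibration point:
#' offset = spo2_ref - slope * r_cal.
#'
#' @param r_cal R-value measured at the calibration session.
#' @param spo2_ref reference saturation, % (0 < spo2_ref <= 100).
#' @param slope population R-curve slope, % per unit R (must be negative).
#' @param model a [calibration_model()] to complete.
#' @return the model with `spo2_slope`/`spo2_offset` filled in.
#' @export
calibrate_spo2 <- function(r_cal, spo2_ref, slope = SPO2_SLOPE_DEFAULT,
                           model = calibration_model()) {
  if (slope >= 0) stop("R-curve slope must be negative")
  if (!(spo2_ref > 0 && spo2_ref <= 100)) stop("spo2_ref must be in (0, 100]")
  model$spo2_slope <- slope
  model$spo2_offset <- spo2_ref - slope * r_cal
  model
}

#' Estimate SpO2 from an R-value
#'
#' Absolute mode requires a per-subject calibration; the result is clipped
#' to (0, 100].  Without calibration only relative changes are defined:
#' see [spo2_change()].
#'
#' @param model an SpO2-calibrated [calibration_model()].
#' @param r measured R-value.
#' @return saturation, %.
#' @export
estimate_spo2 <- function(model, r) {
  stopifnot(inherits(model, "calibration_model"))
  if (is.na(model$spo2_offset))
    stop("model is not SpO2-calibrated; absolute SpO2 requires a per-subject offset")
  pmin(100, pmax(1e-9, model$spo2_slope * r + model$spo2_offset))
}

#' Relative SpO2 change from an R-value change (no calibration needed)
#'
#' @param r,r_ref current and reference R-values.
#' @param slope population R-curve slope, % per unit R.
#' @return delta saturation, percentage points.
#' @export
spo2_change <- function(r, r_ref, slope = SPO2_SLOPE_DEFAULT) {
  if (slope >= 0) stop("R-curve slope must be negative")
  slope * (r - r_ref)
}

#' Estimate stroke volume from the BCG J-K amplitude
#'
#' Linear map with population coefficients: sv = sv_intercept +
#' sv_gain * jk_amplitude.  This functional form is a deliberately simple
#' stand-in for published BCG stroke-volume algorithms; coefficients are
#' fit on training data with [fit_sv_model()].
#'
#' @param fiducials a `fiducial_set` with a defined `jk_amplitude`, or a
#'   bare numeric J-K amplitude in N.
#' @param model a [calibration_model()].
#' @return a list `(sv, flags)`; missing fiducials yield `NA` flagged
#'   `"no_bcg_fiducials"`, a negative estimate is clamped to 0 and flagged.
#' @export
estimate_sv <- function(fiducials, model) {
  jk <- if (inherits(fiducials, "fiducial_set")) fiducials$jk_amplitude
        else as.numeric(fiducials)
  if (is.null(jk) || !is.finite(jk))
    return(list(sv = NA_real_, flags = "no_bcg_fiducials"))
  sv <- model$sv_intercept + model$sv_gain * jk
  flags <- character(0)
  if (sv < 0) { sv <- 0; flags <- "negative_sv" }
  list(sv = sv, flags = flags)
}

#' Fit population stroke-volume coefficients on a training set
#'
#' Ordinary least squares of reference SV on measured J-K amplitude.
#'
#' @param jk measured J-K amplitudes, N.
#' @param sv_ref reference stroke volumes, mL.
#' @return `c(sv_intercept, sv_gain)`.
#' @export
fit_sv_model <- function(jk, sv_ref) {
  stopifnot(length(jk) == length(sv_ref), length(jk) >= 2)
  co <- stats::coef(stats::lm(sv_ref ~ jk))
  c(sv_intercept = unname(co[1]), sv_gain = unname(co[2]))
}

#' Cardiac output from stroke volume and heart rate
#'
#' CO is the product of stroke volume and heart rate, reported in L/min.
#'
#' @param sv stroke volume, mL (>= 0).
#' @param hr heart rate, bpm (> 0).
#' @return cardiac output, L/min.
#' @export
compute_co <- function(sv, hr) {
  if (any(sv < 0)) stop("sv must be >= 0")
  if (any(hr <= 0)) stop("hr must be positive")
  sv * hr / 1000
}
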
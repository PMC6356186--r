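# Plain-text formats: recording CSV + metadata sidecar + annotation file,
# per-subject calibration key-value files, estimate CSV rows.

#' Write a recording to CSV with a metadata sidecar
#'
#' Creates `<stem>.csv` (columns `time_s, ecg_mv, bcg_n, ppg_red, ppg_ir`),
#' `<stem>.meta` (key: value lines with fs, subject_id, duration) and, when
#' annotations are present, `<stem>.events.csv` (`event_type, time_s,
#' label`).
#'
#' @param recording a `recording`.
#' @param stem file path without extension.
#' @return the stem, invisibly.
#' @export
write_recording <- function(recording, stem) {
  stopifnot(inherits(recording, "recording"))
  n <- length(recording$ecg)
  df <- data.frame(
    time_s = (seq_len(n) - 1) / recording$fs,
    ecg_mv = recording$ecg, bcg_n = recording$bcg,
    ppg_red = recording$ppg_red, ppg_ir = recording$ppg_ir
  )
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  writeLines(c(
    sprintf("fs: %.10g", recording$fs),
    sprintf("subject_id: %s", recording$subject_id),
    sprintf("duration: %.10g", recording$duration)
  ), paste0(stem, ".meta"))
  if (!is.null(recording$annotations))
    utils::write.csv(recording$annotations, paste0(stem, ".events.csv"),
                     row.names = FALSE)
  invisible(stem)
}

read_keyvalue <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  vals <- lapply(kv, function(p) trimws(p[2]))
  names(vals) <- vapply(kv, function(p) trimws(p[1]), character(1))
  vals
}

#' Read a recording written by [write_recording()]
#'
#' @param stem file path without extension.
#' @return a `recording` (without ground truth).
#' @export
read_recording <- function(stem) {
  df <- utils::read.csv(paste0(stem, ".csv"))
  meta <- read_keyvalue(paste0(stem, ".meta"))
  ann <- NULL
  ev <- paste0(stem, ".events.csv")
  if (file.exists(ev)) ann <- utils::read.csv(ev)
  new_recording(
    fs = as.numeric(meta$fs), ecg = df$ecg_mv, bcg = df$bcg_n,
    ppg_red = df$ppg_red, ppg_ir = df$ppg_ir,
    duration = as.numeric(meta$duration),
    subject_id = meta$subject_id, annotations = ann
  )
}

#' Write a calibration model as a plain-text key-value file
#' @param model a `calibration_model`.
#' @param path output file.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  fields <- c("subject_id", "aortic_length", "bp_slope_s", "bp_slope_d",
              "bp_offset_s", "bp_offset_d", "spo2_slope", "spo2_offset",
              "sv_intercept", "sv_gain", "bp_predictor")
  writeLines(vapply(fields, function(f)
    sprintf("%s: %s", f, format(model[[f]], digits = 15)), character(1)), path)
  invisible(path)
}

#' Read a calibration model written by [write_calibration()]
#' @param path input file.
#' @return a `calibration_model`.
#' @export
read_calibration <- function(path) {
  kv <- read_keyvalue(path)
  num <- function(f) as.numeric(kv[[f]])
  calibration_model(
    subject_id = kv$subject_id, aortic_length = num("aortic_length"),
    bp_slope_s = num("bp_slope_s"), bp_slope_d = num("bp_slope_d"),
    bp_offset_s = num("bp_offset_s"), bp_offset_d = num("bp_offset_d"),
    spo2_slope = num("spo2_slope"), spo2_offset = num("spo2_offset"),
    sv_intercept = num("sv_intercept"), sv_gain = num("sv_gain"),
    bp_predictor = kv$bp_predictor
  )
}
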
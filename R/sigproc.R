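# Beat detection, quality gating, ECG-referenced ensemble averaging and
# fiducial extraction.

# Zero-phase Butterworth band-pass with reflection padding to suppress the
# filtfilt edge transient.  `band` in Hz; either edge may be NA to fall back
# to high- or low-pass only.
bandpass <- function(x, fs, band, order = 2) {
  lo <- band[1]; hi <- band[2]
  ny <- fs / 2
  if (!is.na(hi) && hi >= ny) hi <- NA
  pad <- min(length(x) - 1L, round(2 * fs))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[seq(length(x) - pad + 1L, length(x))]))
  if (!is.na(lo) && !is.na(hi)) {
    bf <- signal::butter(order, c(lo, hi) / ny, type = "pass")
  } else if (!is.na(lo)) {
    bf <- signal::butter(order, lo / ny, type = "high")
  } else {
    bf <- signal::butter(order, hi / ny, type = "low")
  }
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1L):(pad + length(x))]
}

new_beat_series <- function(r_times, accepted = rep(TRUE, length(r_times)),
                            rejection_reason = rep(NA_character_, length(r_times)),
                            flagged = FALSE) {
  stopifnot(!is.unsorted(r_times, strictly = TRUE) || length(r_times) <= 1L)
  structure(list(r_times = r_times,
                 rr = if (length(r_times) > 1) diff(r_times) else numeric(0),
                 accepted = accepted, rejection_reason = rejection_reason,
                 flagged = flagged),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series: %d beats, %d accepted%s>\n",
              length(x$r_times), sum(x$accepted),
              if (isTRUE(x$flagged)) ", flagged" else ""))
  invisible(x)
}

#' Detect R peaks in a single-lead ECG
#'
#' Derivative-energy detector in the Pan-Tompkins spirit: band-pass,
#' differentiate, square, moving-window integrate, adaptive threshold with a
#' refractory period, then refine each detection to the local maximum of the
#' band-passed ECG.
#'
#' @param ecg ECG samples, mV.
#' @param fs sampling rate, Hz.
#' @param band detection band-pass, Hz.
#' @param refractory minimum separation between detections, s.
#' @return a `beat_series`; all-flat or all-NA input yields an empty,
#'   flagged series.
#' @export
detect_r_peaks <- function(ecg, fs, band = c(0.5, 40), refractory = 0.25) {
  if (length(ecg) < 2 * fs) stop("need at least 2 s of ECG")
  if (all(!is.finite(ecg)) || stats::sd(ecg, na.rm = TRUE) == 0 ||
      !is.finite(stats::sd(ecg, na.rm = TRUE)))
    return(new_beat_series(numeric(0), logical(0), character(0), flagged = TRUE))
  ecg[!is.finite(ecg)] <- 0
  xf <- bandpass(ecg, fs, band)
  d <- c(0, diff(xf)) * fs
  env <- stats::filter(d^2, rep(1 / round(0.15 * fs), round(0.15 * fs)),
                       sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  thr <- 0.25 * stats::quantile(env, 0.98)
  if (thr <= 0)
    return(new_beat_series(numeric(0), logical(0), character(0), flagged = TRUE))
  above <- env > thr
  # rising edges of the above-threshold regions are beat candidates
  starts <- which(diff(c(FALSE, above)) == 1)
  ends <- which(diff(c(above, FALSE)) == -1)
  if (!length(starts))
    return(new_beat_series(numeric(0), logical(0), character(0), flagged = TRUE))
  half <- round(0.08 * fs)
  cand <- vapply(seq_along(starts), function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(env[seg])]
  }, integer(1))
  # refine to the R peak of the band-passed ECG
  peaks <- vapply(cand, function(i) {
    w <- max(1L, i - half):min(length(xf), i + half)
    w[which.max(xf[w])]
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refractory: keep the larger of any pair closer than `refractory`
  keep <- logical(length(peaks))
  last <- -Inf; last_i <- 0L
  for (i in seq_along(peaks)) {
    t_i <- (peaks[i] - 1) / fs
    if (t_i - last >= refractory) {
      keep[i] <- TRUE; last <- t_i; last_i <- i
    } else if (xf[peaks[i]] > xf[peaks[last_i]]) {
      keep[last_i] <- FALSE; keep[i] <- TRUE; last <- t_i; last_i <- i
    }
  }
  r_times <- (peaks[keep] - 1) / fs
  new_beat_series(r_times)
}

#' Remove beats with abnormal RR intervals
#'
#' A beat is rejected iff either adjacent RR interval deviates from the
#' running median RR (window 11) by more than `tolerance` (fractional).
#' Diastolic duration and ventricular filling shift beat-by-beat BP and SV,
#' so beats bounding an abnormal interval are unusable for estimation.
#' Timing is never altered; only the accepted flags and reasons change, so
#' the operator is idempotent.
#'
#' @param beats a `beat_series`.
#' @param tolerance fractional deviation from the running median (default 0.20).
#' @param window running-median window (odd, default 11).
#' @return the `beat_series` with updated `accepted`/`rejection_reason`.
#' @export
filter_abnormal_beats <- function(beats, tolerance = 0.20, window = 11) {
  stopifnot(inherits(beats, "beat_series"))
  n <- length(beats$r_times)
  if (n < 3) {
    beats$accepted <- rep(FALSE, n)
    beats$rejection_reason <- rep("too_few", n)
    return(beats)
  }
  rr <- beats$rr
  k <- min(window, if (length(rr) %% 2 == 0) length(rr) - 1 else length(rr))
  if (k < 1) k <- 1
  med <- stats::runmed(rr, k, endrule = "median")
  bad_rr <- abs(rr - med) > tolerance * med
  accepted <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    adj <- c(if (i > 1) bad_rr[i - 1] else FALSE,
             if (i < n) bad_rr[i] else FALSE)
    if (any(adj)) {
      accepted[i] <- FALSE
      reason[i] <- "abnormal_interval"
    }
  }
  beats$accepted <- accepted
  beats$rejection_reason <- reason
  beats
}

#' Recording-level signal quality check
#'
#' A recording is accepted iff it has at least `min_beats` accepted beats,
#' the accepted beats span at least `min_span` seconds, and the fraction of
#' high-power (motion-contaminated) BCG windows does not exceed
#' `max_motion`.
#'
#' @param recording a `recording`.
#' @param beats the `beat_series` computed on it (after
#'   [filter_abnormal_beats()]).
#' @param min_beats,min_span,max_motion thresholds.
#' @param motion_factor a 1-s BCG window counts as motion when its RMS
#'   exceeds this multiple of the median window RMS.
#' @return a list of class `quality_report` with `recording_accepted`,
#'   `n_beats_total`, `n_beats_accepted`, `reasons`, `motion_fraction`.
#' @export
assess_recording <- function(recording, beats, min_beats = 20,
                             min_span = 30, max_motion = 0.2,
                             motion_factor = 5) {
  stopifnot(inherits(recording, "recording"), inherits(beats, "beat_series"))
  reasons <- character(0)
  n_acc <- sum(beats$accepted)
  if (n_acc < min_beats) reasons <- c(reasons, "too_few_beats")
  span <- if (n_acc >= 2) diff(range(beats$r_times[beats$accepted])) else 0
  if (span < min_span) reasons <- c(reasons, "too_short")
  fs <- recording$fs
  nw <- floor(length(recording$bcg) / fs)
  motion_fraction <- 0
  if (nw >= 3) {
    xb <- bandpass(recording$bcg, fs, c(0.5, 20))
    rms <- vapply(seq_len(nw), function(w) {
      idx <- ((w - 1) * fs + 1):(w * fs)
      sqrt(mean(xb[idx]^2))
    }, numeric(1))
    med <- stats::median(rms)
    if (med > 0) motion_fraction <- mean(rms > motion_factor * med)
  }
  if (motion_fraction > max_motion) reasons <- c(reasons, "motion")
  structure(list(
    recording_accepted = length(reasons) == 0,
    n_beats_total = length(beats$r_times),
    n_beats_accepted = n_acc,
    reasons = reasons,
    motion_fraction = motion_fraction
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report: %s, %d/%d beats accepted%s>\n",
              if (x$recording_accepted) "accepted" else "REJECTED",
              x$n_beats_accepted, x$n_beats_total,
              if (length(x$reasons)) paste0(", reasons: ",
                                            paste(x$reasons, collapse = ", "))
              else ""))
  invisible(x)
}

#' ECG-referenced ensemble average of one channel
#'
#' Pointwise mean of beat-aligned segments over the accepted beats; the
#' single-lead ECG R peaks are the alignment reference.  Beats whose window
#' falls outside the recording are skipped; the window is truncated to the
#' minimum accepted RR interval.
#'
#' @param recording a `recording`.
#' @param beats a `beat_series` on this recording.
#' @param channel one of `"ecg"`, `"bcg"`, `"ppg_red"`, `"ppg_ir"`.
#' @param window `c(before, after)` seconds around the R peak.
#' @param band optional band-pass (Hz) applied to the channel first.
#' @return a list of class `ensemble_waveform` with `channel`, `rel_time`,
#'   `amplitude`, `n_beats`.
#' @export
ensemble_average <- function(recording, beats, channel = "bcg",
                             window = c(0.2, 0.8), band = NULL) {
  stopifnot(inherits(recording, "recording"), inherits(beats, "beat_series"))
  channel <- match.arg(channel, c("ecg", "bcg", "ppg_red", "ppg_ir"))
  r_acc <- beats$r_times[beats$accepted]
  if (!length(r_acc)) stop("no accepted beats; recording unusable")
  fs <- recording$fs
  x <- recording[[channel]]
  if (!is.null(band)) x <- bandpass(x, fs, band)
  rr_acc <- diff(r_acc)              # truncate to the shortest accepted RR
  if (length(rr_acc)) window[2] <- min(window[2], min(rr_acc))
  i_before <- round(window[1] * fs)
  i_after <- round(window[2] * fs)
  offs <- (-i_before):i_after
  r_idx <- round(r_acc * fs) + 1L
  ok <- r_idx - i_before >= 1L & r_idx + i_after <= length(x)
  r_idx <- r_idx[ok]
  if (!length(r_idx)) stop("no beat window fits inside the recording")
  m <- vapply(r_idx, function(i) x[i + offs], numeric(length(offs)))
  structure(list(channel = channel, rel_time = offs / fs,
                 amplitude = rowMeans(m), n_beats = length(r_idx)),
            class = "ensemble_waveform")
}

#' @export
print.ensemble_waveform <- function(x, ...) {
  cat(sprintf("<ensemble_waveform %s: [%.2f, %.2f] s rel. R, %d beats>\n",
              x$channel, min(x$rel_time), max(x$rel_time), x$n_beats))
  invisible(x)
}

local_minima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] < y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n]) + 1L
}

#' Locate the BCG I, J and K waves on an ensemble-averaged beat
#'
#' J is the global maximum in the search window after R (earliest sample on
#' ties); I is the local minimum immediately preceding J; K the local
#' minimum immediately following.  The J-K amplitude is amp(J) - amp(K).
#'
#' @param ens an `ensemble_waveform` of the BCG channel.
#' @param search_window `c(lo, hi)` seconds after R for the J wave.
#' @return a list of class `fiducial_set` (BCG part): `bcg_i`, `bcg_j`,
#'   `bcg_k` (each `time`/`amplitude`), `jk_amplitude`, `flags`.
#' @export
locate_bcg_fiducials <- function(ens, search_window = c(0.05, 0.40)) {
  stopifnot(inherits(ens, "ensemble_waveform"))
  if (ens$channel != "bcg") stop("ensemble is not a BCG waveform")
  t <- ens$rel_time; y <- ens$amplitude
  win <- which(t >= search_window[1] & t <= search_window[2])
  if (length(win) < 3) stop("J search window outside the ensemble")
  i_j <- win[which.max(y[win])]       # which.max returns the earliest tie
  pre <- local_minima(y[seq_len(i_j)])
  post <- local_minima(y[i_j:length(y)])
  flags <- character(0)
  if (!length(pre) || !length(post)) {
    return(structure(list(bcg_i = NULL, bcg_j = list(time = t[i_j], amplitude = y[i_j]),
                          bcg_k = NULL, jk_amplitude = NA_real_,
                          flags = "no_extrema"), class = "fiducial_set"))
  }
  i_i <- max(pre)
  i_k <- i_j + min(post) - 1L
  structure(list(
    bcg_i = list(time = t[i_i], amplitude = y[i_i]),
    bcg_j = list(time = t[i_j], amplitude = y[i_j]),
    bcg_k = list(time = t[i_k], amplitude = y[i_k]),
    jk_amplitude = y[i_j] - y[i_k],
    flags = flags
  ), class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  if (!is.null(x$bcg_j))
    cat(sprintf("<fiducial_set: J %.3f s, J-K %.3f N%s>\n",
                x$bcg_j$time, x$jk_amplitude,
                if (length(x$flags)) paste0(", flags: ", paste(x$flags, collapse = ","))
                else ""))
  invisible(x)
}

#' Locate the PPG foot on an ensemble-averaged pulse
#'
#' Intersecting-tangents method: the foot is the intersection of the
#' horizontal line through the pre-systolic minimum and the tangent at the
#' point of maximum upslope.  Offset-invariant by construction.  The search
#' starts after the BCG J window so the located foot is the pulse following
#' ejection.
#'
#' @param ens an `ensemble_waveform` of a PPG channel.
#' @param search_start earliest rel. time (s after R) for the pulse peak
#'   search.
#' @param min_pulsatility minimum (max - min)/|mean| for the ensemble to
#'   count as pulsatile.
#' @param pre_window how far before the maximum-upslope point (s) the
#'   pre-systolic minimum is searched; keeps residual baseline wander from
#'   hijacking the minimum.
#' @return foot time (s relative to the R peak), or `NA` with attribute
#'   `flag = "non_pulsatile"` when no pulse is present.
#' @export
locate_ppg_foot <- function(ens, search_start = 0.05, min_pulsatility = 1e-4,
                            pre_window = 0.12) {
  stopifnot(inherits(ens, "ensemble_waveform"))
  if (!ens$channel %in% c("ppg_red", "ppg_ir"))
    stop("ensemble is not a PPG waveform")
  t <- ens$rel_time; y <- ens$amplitude
  sel <- t >= search_start
  t <- t[sel]; y <- y[sel]
  rng <- max(y) - min(y)
  if (rng <= min_pulsatility * max(abs(mean(y)), 1e-12)) {
    out <- NA_real_
    attr(out, "flag") <- "non_pulsatile"
    return(out)
  }
  tangent_foot(t, y, pre_window = pre_window)
}

#' Measure the AC and DC components of an ensemble-averaged PPG pulse
#'
#' AC is the peak-to-foot amplitude (max - min of the ensemble); DC is the
#' mean optical level over the ensemble window.  Both in the channel's
#' arbitrary units; the AC/DC ratio is invariant to LED gain.
#'
#' @param ens an `ensemble_waveform` of a PPG channel.
#' @param min_pulsatility AC/DC ratio below which the pulse is flagged
#'   non-pulsatile.
#' @return a list `(ac, dc, flags)`.
#' @export
measure_ppg_ac_dc <- function(ens, min_pulsatility = 1e-4) {
  stopifnot(inherits(ens, "ensemble_waveform"))
  if (!ens$channel %in% c("ppg_red", "ppg_ir"))
    stop("ensemble is not a PPG waveform")
  y <- ens$amplitude
  dc <- mean(y)
  if (dc <= 0) stop("non-positive DC optical level")
  ac <- max(y) - min(y)
  flags <- if (ac <= min_pulsatility * dc) "non_pulsatile" else character(0)
  list(ac = ac, dc = dc, flags = flags)
}
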
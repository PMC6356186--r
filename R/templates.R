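# Parametric beat templates for the forward generator.
#
# Each template is evaluated on the recording's own sample grid so that the
# generator's annotated fiducials are exact at sample resolution.  Unit
# templates are characterized numerically (J time, J-K amplitude, tangent
# foot offset) once per (fs, parameter) combination and the results are used
# to place and scale the per-beat copies.

# Sum-of-Gaussians ECG beat (P-QRS-T), peak R amplitude ~1 mV at u = 0.
ecg_beat_template <- function(u) {
  g <- function(a, mu, s) a * exp(-((u - mu)^2) / (2 * s^2))
  g(0.10, -0.200, 0.040) +   # P
    g(-0.12, -0.040, 0.018) + # Q
    g(1.00, 0.000, 0.012) +   # R
    g(-0.20, 0.035, 0.015) +  # S
    g(0.28, 0.300, 0.070)     # T
}

# Gaussian-enveloped cosine BCG complex: the central maximum is the J wave,
# the flanking minima are I and K.  Smooth everywhere, so zero-phase
# band-pass filtering neither rings nor shifts the extrema.
bcg_beat_template <- function(u, f = 7, sigma = 0.08) {
  exp(-(u^2) / (2 * sigma^2)) * cos(2 * pi * f * u)
}

# Log-normal-rise PPG pulse with a smooth taper back to baseline, peak 1.
ppg_beat_template <- function(u, m = 0.18, s = 0.45, taper_from = 0.50,
                              taper_to = 0.68) {
  y <- numeric(length(u))
  pos <- u > 0
  y[pos] <- exp(-(log(u[pos] / m))^2 / (2 * s^2))
  w <- rep(1, length(u))
  ramp <- u > taper_from & u < taper_to
  w[ramp] <- cos(0.5 * pi * (u[ramp] - taper_from) / (taper_to - taper_from))^2
  w[u >= taper_to] <- 0
  y * w
}

# Intersecting-tangent foot of a pulse: intersection of the horizontal
# through the pre-systolic minimum with the tangent at maximum upslope.
# The upslope is located first (the most wander-robust landmark) on a
# lightly smoothed copy; the minimum is then searched in a short window
# just before it.  Returns a continuous (sub-sample) time.
tangent_foot <- function(u, y, pre_window = 0.12, up_window = 0.30,
                         smooth_s = 0.02) {
  n <- length(y)
  if (n < 5L) return(NA_real_)
  dt <- u[2] - u[1]
  w <- max(1L, round(smooth_s / dt))
  if (w %% 2 == 0) w <- w + 1L
  ys <- if (w > 1) {
    half <- (w - 1L) %/% 2L
    yp <- c(rep(y[1], half), y, rep(y[n], half))
    f <- as.numeric(stats::filter(yp, rep(1 / w, w), sides = 2))
    f[(half + 1L):(half + n)]
  } else y
  i_peak <- which.max(ys)
  if (i_peak < 3L) return(NA_real_)
  d <- c(0, diff(ys))
  up_region <- which(u >= u[i_peak] - up_window & u <= u[i_peak])
  up_region <- up_region[up_region > 1L]
  if (length(up_region) < 2L) return(NA_real_)
  i_up <- up_region[which.max(d[up_region])]
  pre <- which(u >= u[i_up] - pre_window & u <= u[i_up])
  if (length(pre) < 2L) return(NA_real_)
  i_min <- pre[which.min(ys[pre])]
  slope <- d[i_up] / dt
  if (!is.finite(slope) || slope <= 0 || i_min >= i_peak) return(NA_real_)
  u[i_up] + (ys[i_min] - ys[i_up]) / slope
}

# Numeric characterization of the unit templates on a dt grid.
characterize_bcg_template <- function(fs, f = 7, sigma = 0.08) {
  u <- seq(-4 * sigma, 4 * sigma, by = 1 / fs)
  y <- bcg_beat_template(u, f = f, sigma = sigma)
  i_j <- which.max(y)
  i_k <- i_j + which.min(y[i_j:length(y)]) - 1L
  i_i <- which.min(y[seq_len(i_j)])
  list(
    j_time = u[i_j], i_time = u[i_i], k_time = u[i_k],
    jk_unit = y[i_j] - y[i_k], half_support = 4 * sigma
  )
}

characterize_ppg_template <- function(fs, m = 0.18, s = 0.45) {
  u <- seq(0, 0.70, by = 1 / fs)
  y <- ppg_beat_template(u, m = m, s = s)
  list(
    foot_offset = tangent_foot(u, y),
    peak_time = u[which.max(y)],
    amp_unit = max(y) - min(y),
    support = 0.70
  )
}

# Add `amp * template(t - at)` into a signal vector in place (returned).
add_template <- function(x, fs, at, amp, template_fun, half_before, half_after) {
  n <- length(x)
  i0 <- max(1L, floor((at - half_before) * fs) + 1L)
  i1 <- min(n, ceiling((at + half_after) * fs) + 1L)
  if (i0 > i1) return(x)
  idx <- i0:i1
  u <- (idx - 1L) / fs - at
  x[idx] <- x[idx] + amp * template_fun(u)
  x
}
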
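# Device-validation statistics: Bland-Altman agreement, LoA conversions,
# AAMI/ISO compliance checks, BMI stratification.

#' Bland-Altman agreement analysis
#'
#' Differences are device minus gold standard.  `bias` is their mean, `sd`
#' the sample (n-1) standard deviation, the limits of agreement are
#' bias +/- 1.96*sd, and `arms` is the root-mean-square error (n divisor).
#'
#' @param seat device estimates.
#' @param gold paired gold-standard values (same length, n >= 2).
#' @return an object of class `bland_altman_result` with `n`, `bias`,
#'   `sd`, `loa_halfwidth`, `loa_interval`, `arms`, and the differences.
#' @export
bland_altman <- function(seat, gold) {
  if (length(seat) != length(gold)) stop("seat and gold differ in length")
  n <- length(seat)
  if (n < 2) stop("need at least 2 paired values")
  d <- seat - gold
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(
    n = n, bias = bias, sd = s,
    loa_halfwidth = 1.96 * s,
    loa_interval = c(bias - 1.96 * s, bias + 1.96 * s),
    arms = sqrt(mean(d^2)),
    differences = d
  ), class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman: n=%d, bias %.2f (SD %.2f), LoA [%.2f, %.2f], A_RMS %.2f>\n",
              x$n, x$bias, x$sd, x$loa_interval[1], x$loa_interval[2], x$arms))
  invisible(x)
}

#' Bland-Altman plot (differences vs gold standard)
#'
#' @param x a `bland_altman_result`.
#' @param gold the gold-standard values the differences were computed
#'   against (x axis); defaults to the index.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman_result <- function(x, gold = seq_len(x$n), ...) {
  graphics::plot(gold, x$differences,
                 ylab = "device - gold", xlab = "gold standard",
                 ylim = range(c(x$differences, x$loa_interval)), ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = x$loa_interval, lty = 2)
  invisible(x)
}

#' Convert an A_RMS accuracy bound to limits of agreement
#'
#' Assuming zero mean, an RMS error converts to a limits-of-agreement
#' half-width by multiplying by 1.96 (e.g. the pulse-oximetry bound of
#' 3.5% RMS corresponds to 6.9% LoA).
#'
#' @param arms RMS error (>= 0).
#' @return 1.96 * arms.
#' @export
loa_from_arms <- function(arms) {
  if (any(arms < 0)) stop("arms must be >= 0")
  1.96 * arms
}

#' Check a Bland-Altman result against a device standard
#'
#' `AAMI_BP`: |bias| <= 5 mm Hg and SD <= 8 mm Hg.  `ISO_SPO2`:
#' A_RMS <= 3.5%.  The verdict's `margin` is the smallest slack across the
#' standard's criteria (negative when failing).
#'
#' @param result a `bland_altman_result`.
#' @param standard `"AAMI_BP"` or `"ISO_SPO2"`.
#' @return a list of class `compliance_verdict` with `standard`, `pass`,
#'   `margin`, `margins`.
#' @export
check_compliance <- function(result, standard = c("AAMI_BP", "ISO_SPO2")) {
  stopifnot(inherits(result, "bland_altman_result"))
  standard <- match.arg(standard)
  margins <- switch(standard,
    AAMI_BP = c(bias = 5 - abs(result$bias), sd = 8 - result$sd),
    ISO_SPO2 = c(arms = 3.5 - result$arms)
  )
  structure(list(standard = standard, pass = all(margins >= 0),
                 margin = min(margins), margins = margins),
            class = "compliance_verdict")
}

#' @export
print.compliance_verdict <- function(x, ...) {
  cat(sprintf("<%s: %s (margin %.2f)>\n", x$standard,
              if (x$pass) "PASS" else "FAIL", x$margin))
  invisible(x)
}

#' Default BMI strata (kg/m^2), half-open [low, high)
#' @return a data.frame of bin edges.
#' @export
bmi_bins_default <- function() {
  data.frame(low = c(-Inf, 18.5, 25, 30), high = c(18.5, 25, 30, Inf))
}

#' Stratify estimation errors by BMI
#'
#' Each record falls in exactly one half-open bin [low, high) or none;
#' per-bin statistics are those of [bland_altman()] applied to the bin's
#' differences (bins with n < 2 report NA spread).
#'
#' @param records data.frame with columns `difference` and `bmi`.
#' @param bins data.frame with non-overlapping `low`/`high` edges.
#' @return a data.frame with one row per bin: `low`, `high`, `n`, `bias`,
#'   `sd`, `loa_halfwidth`.
#' @export
stratify <- function(records, bins = bmi_bins_default()) {
  stopifnot(all(c("difference", "bmi") %in% names(records)),
            all(c("low", "high") %in% names(bins)))
  o <- order(bins$low)
  bins <- bins[o, ]
  if (any(bins$high <= bins$low)) stop("each bin needs high > low")
  if (nrow(bins) > 1 && any(bins$low[-1] < bins$high[-nrow(bins)]))
    stop("bins overlap")
  out <- do.call(rbind, lapply(seq_len(nrow(bins)), function(i) {
    d <- records$difference[records$bmi >= bins$low[i] & records$bmi < bins$high[i]]
    n <- length(d)
    data.frame(low = bins$low[i], high = bins$high[i], n = n,
               bias = if (n) mean(d) else NA_real_,
               sd = if (n >= 2) stats::sd(d) else NA_real_,
               loa_halfwidth = if (n >= 2) 1.96 * stats::sd(d) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Percent variation between two calibration-curve slopes
#'
#' 100 * |s1 - s2| / |mean(s1, s2)|, rounded to the nearest integer for
#' reporting (e.g. slopes -36.9 and -33.1 vary by 11%).
#'
#' @param s1,s2 slopes of the same sign, nonzero.
#' @param digits rounding for the reported value (0 = nearest integer).
#' @return percent variation.
#' @export
percent_slope_variation <- function(s1, s2, digits = 0) {
  if (s1 == 0 || s2 == 0) stop("slopes must be nonzero")
  if (sign(s1) != sign(s2)) stop("slopes have opposite signs")
  round(100 * abs(s1 - s2) / abs(mean(c(s1, s2))), digits)
}
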
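# Matrix-based calibration: unweighted (default) least squares on analyte/IS
# response ratio vs nominal concentration, the associated regression
# statistics (r, S_a, S_b, S_y/x), back-calculation, and the signal-ratio +
# accuracy/precision determination of LLOD/LLOQ.

#' Fit a calibration line
#'
#' Ordinary least squares of response ratio on concentration with the full
#' set of regression diagnostics used in bioanalytical reporting:
#' Pearson's r, `S_y/x = sqrt(SSres / (n - 2))`,
#' `S_b = S_y/x / sqrt(sum((x - xbar)^2))` and
#' `S_a = S_y/x * sqrt(sum(x^2) / (n * sum((x - xbar)^2)))`.
#' Optional `1/x` or `1/x^2` weighting replaces the sums by their weighted
#' analogues.
#'
#' @param conc Nominal concentrations (ng/mL); at least 3 distinct levels.
#' @param response_ratio Analyte/IS peak response ratios.
#' @param analyte Label stored on the curve.
#' @param weighting `"none"` (default), `"1/x"` or `"1/x^2"`.
#' @return An object of class `calibration_curve` with fields `intercept_a`,
#'   `slope_b`, `r`, `s_a`, `s_b`, `s_yx`, `range_low`, `range_high`,
#'   `n_points`.
#' @export
fit_calibration <- function(conc, response_ratio, analyte = "analyte",
                            weighting = c("none", "1/x", "1/x^2")) {
  weighting <- match.arg(weighting)
  x <- as.numeric(conc); y <- as.numeric(response_ratio)
  if (length(x) != length(y)) stop("conc and response_ratio lengths differ")
  if (length(unique(x)) < 3) stop("need at least 3 distinct concentration levels")
  n <- length(x)
  w <- switch(weighting, none = rep(1, n), `1/x` = 1 / x, `1/x^2` = 1 / x^2)
  sw <- sum(w)
  xb <- sum(w * x) / sw; yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  if (sxx == 0) stop("all concentrations identical: slope undefined")
  b <- sum(w * (x - xb) * (y - yb)) / sxx
  a <- yb - b * xb
  res <- y - a - b * x
  ssres <- sum(w * res^2)
  syy <- sum(w * (y - yb)^2)
  r <- if (syy == 0) NA_real_ else sign(b) * sqrt(max(0, 1 - ssres / syy))
  s_yx <- sqrt(ssres / (n - 2))
  s_b <- s_yx / sqrt(sxx)
  s_a <- s_yx * sqrt(sum(w * x^2) / (n * sxx))
  structure(list(analyte = analyte, intercept_a = a, slope_b = b, r = r,
                 s_a = s_a, s_b = s_b, s_yx = s_yx,
                 range_low = min(x), range_high = max(x),
                 n_points = n, weighting = weighting),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: y = %.6g + %.6g x  (r = %.4f, n = %d, %g-%g ng/mL)\n",
              x$analyte, x$intercept_a, x$slope_b, x$r, x$n_points,
              x$range_low, x$range_high))
  cat(sprintf("  S_a = %.3g, S_b = %.3g, S_y/x = %.3g, weighting = %s\n",
              x$s_a, x$s_b, x$s_yx, x$weighting))
  invisible(x)
}

#' Predicted response ratio at given concentrations
#'
#' @param object A `calibration_curve`.
#' @param conc Concentrations (ng/mL).
#' @param ... Ignored.
#' @export
predict.calibration_curve <- function(object, conc, ...) {
  object$intercept_a + object$slope_b * conc
}

#' Back-calculate concentrations from response ratios
#'
#' Inverts the calibration line, `conc = (ratio - a) / b`.  Out-of-range
#' results are flagged, never clamped: negative and below-LLOQ values are
#' returned as-is so validation error statistics stay unbiased; above-range
#' values flag the need for dilution.
#'
#' @param curve A `calibration_curve`.
#' @param response_ratio Observed analyte/IS response ratios.
#' @param lloq Lower quantification bound used for flagging; defaults to the
#'   curve's lowest calibrated level.
#' @return Data frame with columns `conc` and `flag`
#'   (`"ok"`, `"below_lloq"`, `"above_range"`).
#' @export
back_calculate <- function(curve, response_ratio, lloq = curve$range_low) {
  stopifnot(inherits(curve, "calibration_curve"))
  conc <- (response_ratio - curve$intercept_a) / curve$slope_b
  flag <- ifelse(conc > curve$range_high, "above_range",
                 ifelse(conc < lloq, "below_lloq", "ok"))
  data.frame(conc = conc, flag = flag)
}

#' Determine LLOD and LLOQ from blank signals and candidate levels
#'
#' LLOD is the lowest level whose mean signal is at least 3x the mean blank
#' signal; LLOQ the lowest whose mean signal is at least 5x the blank and
#' whose replicate found concentrations satisfy `|Er%| <= 20` and
#' `RSD% <= 20`.  A mean blank signal of exactly zero makes the signal-ratio
#' criteria vacuously true.
#'
#' @param blank_signals Replicate blank responses (>= 1 value).
#' @param levels Data frame with columns `level` (ng/mL), `signal` and
#'   `found` (back-calculated concentration), one row per replicate; at
#'   least 3 replicates per level.
#' @param ratio_llod,ratio_lloq Signal-ratio thresholds (default 3 and 5).
#' @param limit_pct Accuracy/precision limit at the LLOQ (default 20).
#' @return An object of class `limit_determination`: `llod`, `lloq`
#'   (NA when not determinable), `blank_signal`, `status` and a per-level
#'   `diagnostics` data frame.
#' @export
determine_limits <- function(blank_signals, levels,
                             ratio_llod = 3, ratio_lloq = 5, limit_pct = 20) {
  stopifnot(length(blank_signals) >= 1,
            all(c("level", "signal", "found") %in% names(levels)))
  blank <- mean(blank_signals)
  lv <- sort(unique(levels$level))
  diag <- do.call(rbind, lapply(lv, function(l) {
    d <- levels[levels$level == l, ]
    if (nrow(d) < 3) stop("level ", l, ": fewer than 3 replicates")
    ms <- mean(d$signal)
    ap <- accuracy_precision(d$found, l)
    data.frame(level = l, mean_signal = ms,
               signal_ratio = if (blank > 0) ms / blank else Inf,
               er_pct = ap$er_pct, rsd_pct = ap$rsd_pct,
               llod_ok = blank == 0 || ms >= ratio_llod * blank,
               lloq_ok = (blank == 0 || ms >= ratio_lloq * blank) &
                 abs(ap$er_pct) <= limit_pct & ap$rsd_pct <= limit_pct)
  }))
  llod <- if (any(diag$llod_ok)) diag$level[which(diag$llod_ok)[1]] else NA_real_
  lloq <- if (any(diag$lloq_ok)) diag$level[which(diag$lloq_ok)[1]] else NA_real_
  status <- if (is.na(llod) || is.na(lloq)) "not determinable" else "ok"
  structure(list(llod = llod, lloq = lloq, blank_signal = blank,
                 status = status, diagnostics = diag),
            class = "limit_determination")
}

#' Correct a measured concentration for sample dilution
#'
#' @param conc Measured concentration (ng/mL).
#' @param dilution_factor Fold dilution applied before analysis, `>= 1`
#'   (e.g. 5 for a 1:5 dilution).
#' @return Reported concentration, `conc * dilution_factor`.
#' @export
apply_dilution <- function(conc, dilution_factor) {
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1")
  conc * dilution_factor
}
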
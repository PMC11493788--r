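#' @title Detection and quantification limits
#' @name limits
#' @description LOD by the Hubaux-Vos prediction-band construction on the
#'   linear (lowest four levels) portion of the calibration curve, with a
#'   Currie-style weighting correction for heteroscedastic data; LOD by
#'   extrapolation of a measured chromatographic signal-to-noise ratio to
#'   S/N = 3; and LOQ assignment as the lowest calibration level meeting
#'   the accuracy and precision acceptance criteria.
NULL

# Per-observation variance scale v(x) implied by a weighting scheme:
# var(y | x) = sigma^2 * v(x), i.e. the reciprocal of the fit weight,
# extrapolated to arbitrary x by the corresponding power law (Currie
# correction). v(0) = 0 for the weighted schemes: the response variance is
# extrapolated to vanish at zero concentration, so the blank decision
# threshold is driven by calibration parameter uncertainty.
variance_scale <- function(weighting, x) {
  switch(match.arg(weighting, WEIGHTINGS),
         "none" = rep(1, length(x)),
         "1/x" = x,
         "1/x^2" = x^2)
}

#' Hubaux-Vos limit of detection
#'
#' Fits a weighted straight line to the lowest `n_levels` calibration
#' levels. The decision threshold `y_c` is the upper `(1 - alpha)`
#' one-sided prediction bound of the fit at x = 0; the LOD is the smallest
#' concentration whose lower `(1 - beta)` prediction bound reaches `y_c`.
#' Prediction variance at x is `sigma^2 * (v(x) + h(x))` where `v(x)` is
#' the weighting's variance power law (see Currie correction note in the
#' source) and `h(x)` the hat term `c(1,x)' (X'WX)^{-1} c(1,x)`.
#'
#' @param records calibrator records; only the `n_levels` lowest levels
#'   are used.
#' @param weighting weighting scheme (`"none"`, `"1/x"`, `"1/x^2"`).
#' @param alpha false-positive rate of the decision threshold.
#' @param beta false-negative rate at the detection limit.
#' @param is_concentration IS concentration (ng/mL).
#' @param n_levels number of lowest levels kept (default 4, the linear
#'   portion).
#' @return list: `lod_ng_ml`, `y_c` (decision threshold on the response
#'   scale), `alpha`, `beta`, `n_points_used`, and the underlying linear
#'   `model`.
#' @export
hubaux_vos_lod <- function(records, weighting = "1/x^2", alpha = 0.05,
                           beta = 0.05, is_concentration = 20,
                           n_levels = 4) {
  if (!(alpha > 0 && alpha < 0.5 && beta > 0 && beta < 0.5)) {
    stop("alpha and beta must lie in (0, 0.5)")
  }
  xy <- records_xy(records, is_concentration)
  keep_levels <- sort(unique(xy$x))[seq_len(min(n_levels,
                                                length(unique(xy$x))))]
  if (length(keep_levels) < 3) stop("need >= 3 distinct low levels")
  xy <- xy[xy$x %in% keep_levels, ]
  n <- nrow(xy)
  w <- weight_for(weighting, xy$x)
  fit <- stats::lm(y ~ x, data = xy, weights = w)
  b <- stats::coef(fit)
  if (b["x"] <= 0) stop("non-positive slope: no detection capability")
  s2 <- sum(w * stats::residuals(fit)^2) / (n - 2)

  X <- cbind(1, xy$x)
  xtwx_inv <- solve(crossprod(X, w * X))
  hat_term <- function(x) {
    vapply(x, function(xi) {
      v <- c(1, xi)
      drop(v %*% xtwx_inv %*% v)
    }, numeric(1))
  }
  pred_sd <- function(x) sqrt(s2 * (variance_scale(weighting, x) +
                                      hat_term(x)))

  t_a <- stats::qt(1 - alpha, n - 2)
  t_b <- stats::qt(1 - beta, n - 2)
  y_c <- unname(b[1] + t_a * pred_sd(0))

  if (s2 <= 0 || pred_sd(0) == 0) {
    return(list(lod_ng_ml = 0, y_c = y_c, alpha = alpha, beta = beta,
                n_points_used = n, model = fit))
  }

  g <- function(x) unname(b[1] + b[2] * x - t_b * pred_sd(x)) - y_c
  upper <- max(keep_levels) * 2
  while (g(upper) < 0 && upper < max(keep_levels) * 1e6) upper <- upper * 4
  if (g(upper) < 0) {
    stop("prediction bands never separate: no finite detection limit")
  }
  x_d <- stats::uniroot(g, lower = 0, upper = upper, tol = 1e-12)$root

  list(lod_ng_ml = x_d * is_concentration, y_c = y_c, alpha = alpha,
       beta = beta, n_points_used = n, model = fit)
}

#' Construct a chromatogram
#'
#' @param time regular time grid, minutes.
#' @param intensity intensities, same length as `time`.
#' @param peak_window `(start, end)` minutes containing the peak.
#' @param noise_window `(start, end)` minutes of analyte-free baseline;
#'   must be disjoint from the peak window and inside the time range.
#' @return a `chromatogram` list.
#' @export
chromatogram <- function(time, intensity, peak_window, noise_window) {
  stopifnot(length(time) == length(intensity))
  rng <- range(time)
  ok_window <- function(wdw) length(wdw) == 2 && wdw[1] < wdw[2] &&
    wdw[1] >= rng[1] && wdw[2] <= rng[2]
  if (!ok_window(peak_window) || !ok_window(noise_window)) {
    stop("windows must be ordered and inside the time range")
  }
  if (max(peak_window[1], noise_window[1]) <
      min(peak_window[2], noise_window[2])) {
    stop("peak and noise windows must be disjoint")
  }
  structure(list(time = time, intensity = intensity,
                 peak_window = peak_window, noise_window = noise_window),
            class = "chromatogram")
}

#' Measure chromatographic signal-to-noise
#'
#' S/N = (maximum intensity in the peak window minus the median of the
#' noise window) divided by the standard deviation of the noise window
#' (RMS noise convention, stable for short windows).
#'
#' @param chrom a [chromatogram()].
#' @return the signal-to-noise ratio.
#' @export
measure_sn <- function(chrom) {
  stopifnot(inherits(chrom, "chromatogram"))
  in_window <- function(wdw) chrom$time >= wdw[1] & chrom$time <= wdw[2]
  noise <- chrom$intensity[in_window(chrom$noise_window)]
  peak <- chrom$intensity[in_window(chrom$peak_window)]
  noise_sd <- stats::sd(noise)
  if (noise_sd == 0) stop("noiseless trace: S/N undefined")
  (max(peak) - stats::median(noise)) / noise_sd
}

#' Extrapolate an LOD from a measured S/N
#'
#' Assuming signal proportional to concentration, the concentration at
#' which S/N = 3 is `3 * conc / sn_measured`. Callers average the result
#' over replicate injections.
#'
#' @param sn_measured measured signal-to-noise ratio(s), > 0.
#' @param conc concentration at which S/N was measured, ng/mL.
#' @return LOD estimate(s) in ng/mL.
#' @examples
#' extrapolate_lod_sn(600, 2)  # 0.01 ng/mL
#' @export
extrapolate_lod_sn <- function(sn_measured, conc) {
  if (any(sn_measured <= 0)) stop("sn_measured must be > 0")
  if (any(conc <= 0)) stop("conc must be > 0")
  3 * conc / sn_measured
}

#' Assign the limit of quantification
#'
#' The LOQ is the lowest calibration level at which every accuracy entry
#' is within +/- `bias_limit` percent and every precision entry is below
#' `cv_limit` percent.
#'
#' @param level nominal levels (ng/mL), one per entry; entries may repeat
#'   a level (e.g. intra- and inter-day values).
#' @param bias_pct bias percentages aligned with `level`.
#' @param cv_pct CV percentages aligned with `level`.
#' @param bias_limit acceptance half-width for |bias|, percent (boundary
#'   passes).
#' @param cv_limit acceptance bound for CV, percent (strict: CV equal to
#'   the bound fails).
#' @return list: `loq_ng_ml` (NA when no level passes), `pass` (logical
#'   per unique level), `table` (per-level worst-case bias and CV).
#' @export
assign_loq <- function(level, bias_pct, cv_pct, bias_limit = 20,
                       cv_limit = 20) {
  stopifnot(length(level) == length(bias_pct),
            length(level) == length(cv_pct))
  levels_sorted <- sort(unique(level))
  worst <- t(vapply(levels_sorted, function(l) {
    sel <- level == l
    c(max_abs_bias = max(abs(bias_pct[sel])), max_cv = max(cv_pct[sel]))
  }, numeric(2)))
  pass <- worst[, "max_abs_bias"] <= bias_limit & worst[, "max_cv"] < cv_limit
  loq <- if (any(pass)) min(levels_sorted[pass]) else NA_real_
  list(loq_ng_ml = loq, pass = stats::setNames(pass, levels_sorted),
       table = data.frame(level = levels_sorted, worst, pass = pass,
                          row.names = NULL))
}
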
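#' @title Matrix effect, extraction recovery, process efficiency, and
#'   standard addition
#' @name matrix_recovery
#' @description Decomposition of the post-extraction spike experiment:
#'   set 1 = blank matrix spiked after extraction, set 2 = matrix-free
#'   (neat) reference, set 3 = matrix spiked before extraction. Then
#'   ME% = 100 x mean(set1)/mean(set2) per level (ionization
#'   enhancement/suppression), ER% = 100 x mean(set3)/mean(set1)
#'   (extraction recovery), and PE% = ME% x ER% / 100 (process
#'   efficiency), each averaged over the spike levels. Standard addition
#'   provides matrix-effect-compensated quantification for samples with
#'   measurable intrinsic levels.
NULL

ratio_of_sets <- function(numerator, denominator, label) {
  levels_u <- sort(unique(denominator$level_ng_ml))
  if (!setequal(levels_u, unique(numerator$level_ng_ml))) {
    stop("sets must cover the same spike levels")
  }
  per_level <- vapply(levels_u, function(l) {
    num <- numerator[numerator$level_ng_ml == l, ]
    den <- denominator[denominator$level_ng_ml == l, ]
    if (nrow(num) < 2 || nrow(den) < 2) stop("need >= 2 replicates per level")
    den_mean <- mean(den$area_analyte / den$area_is)
    if (den_mean == 0) stop("zero mean in ", label, " denominator set")
    100 * mean(num$area_analyte / num$area_is) / den_mean
  }, numeric(1))
  mean_pct <- mean(per_level)
  list(per_level = data.frame(level = levels_u, pct = per_level),
       mean_pct = mean_pct,
       rsd_pct = 100 * stats::sd(per_level) / mean_pct)
}

#' Matrix effect (ME%)
#'
#' @param set1 records of blank matrix spiked after extraction.
#' @param set2 records of the matrix-free reference.
#' @param window acceptability window in percent.
#' @return list: `per_level` (level, ME%), `mean_pct`, `rsd_pct` (RSD of
#'   the level means), `ie_pct` (ion enhancement = ME% - 100),
#'   `acceptable` (mean within the window), `classification`.
#' @export
matrix_effect <- function(set1, set2, window = c(85, 115)) {
  r <- ratio_of_sets(set1, set2, "matrix effect")
  ie <- r$mean_pct - 100
  r$ie_pct <- ie
  r$acceptable <- r$mean_pct >= window[1] && r$mean_pct <= window[2]
  r$classification <- classify_ion_enhancement(ie)
  r
}

#' Classify ion enhancement/suppression
#'
#' Substantial enhancement above +50%, moderate between +25% and +50%,
#' suppression below -15% (outside the low edge of the 85-115%
#' acceptability window), acceptable otherwise.
#'
#' @param ie_pct ion enhancement percentage(s) (ME% - 100).
#' @return character vector of classifications.
#' @export
classify_ion_enhancement <- function(ie_pct) {
  vapply(ie_pct, function(ie) {
    if (ie > 50) "substantial enhancement"
    else if (ie > 25) "moderate enhancement"
    else if (ie < -15) "suppression"
    else "acceptable"
  }, character(1))
}

#' Extraction recovery (ER%)
#'
#' @param set3 records spiked before the extraction step.
#' @param set1 records spiked after the extraction step.
#' @param window acceptability window in percent.
#' @return list: `per_level`, `mean_pct`, `rsd_pct`, `acceptable`.
#' @export
extraction_recovery <- function(set3, set1, window = c(85, 115)) {
  r <- ratio_of_sets(set3, set1, "extraction recovery")
  r$acceptable <- r$mean_pct >= window[1] && r$mean_pct <= window[2]
  r
}

#' Process efficiency (PE%)
#'
#' @param me_pct matrix effect percentage.
#' @param er_pct extraction recovery percentage.
#' @return PE% = ME% x ER% / 100 (computed from unrounded components).
#' @examples
#' process_efficiency(128, 93)  # 119.04
#' @export
process_efficiency <- function(me_pct, er_pct) {
  if (any(me_pct <= 0) || any(er_pct <= 0)) {
    stop("ME% and ER% must be > 0")
  }
  me_pct * er_pct / 100
}

#' Full matrix-effect report for one analyte
#'
#' @param set1,set2,set3 the three spike sets (see module description).
#' @param window acceptability window.
#' @return a `matrix_effect_report` list: `me`, `er`, `pe_pct`, `ie_pct`,
#'   `classification`.
#' @export
matrix_effect_report <- function(set1, set2, set3, window = c(85, 115)) {
  me <- matrix_effect(set1, set2, window)
  er <- extraction_recovery(set3, set1, window)
  structure(list(me = me, er = er,
                 pe_pct = process_efficiency(me$mean_pct, er$mean_pct),
                 ie_pct = me$ie_pct,
                 classification = me$classification),
            class = "matrix_effect_report")
}

#' Quantify by standard addition
#'
#' Fits an unweighted line of response on added concentration; the
#' intrinsic concentration is the magnitude of the x-intercept,
#' `a0 / a1`.
#'
#' @param added added concentrations (ng/mL), including zero addition.
#' @param response response ratios aligned with `added`.
#' @param negative_tolerance extrapolated concentrations below
#'   `-negative_tolerance` are flagged (returned NA with a warning).
#' @return list: `conc_ng_ml` (intrinsic concentration), `slope`,
#'   `intercept`.
#' @examples
#' # truth 1.5 ng/mL, slope 0.2
#' standard_addition_quantify(c(0, 2, 4, 8),
#'                            0.2 * (c(0, 2, 4, 8) + 1.5))$conc_ng_ml
#' @export
standard_addition_quantify <- function(added, response,
                                       negative_tolerance = 0.2) {
  stopifnot(length(added) == length(response))
  if (length(unique(added)) < 3) stop("need >= 3 addition levels")
  if (!any(added == 0)) stop("a zero-addition sample is required")
  fit <- stats::lm(response ~ added)
  a1 <- unname(stats::coef(fit)["added"])
  a0 <- unname(stats::coef(fit)["(Intercept)"])
  if (a1 <= 0) stop("non-positive slope: responses must increase with addition")
  conc <- a0 / a1
  if (conc < -negative_tolerance) {
    warning("extrapolated concentration is negative beyond tolerance; flagged")
    conc <- NA_real_
  }
  list(conc_ng_ml = conc, slope = a1, intercept = a0)
}
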
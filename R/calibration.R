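#' @title Weighted calibration: variance assessment, model selection,
#'   fitting, back-calculation
#' @name calibration
#' @description The calibration axes are ratios: the response ratio
#'   `y = analyte peak area / internal standard peak area` is regressed on
#'   the concentration ratio `x = nominal level / IS concentration`.
#'   Replicate variance is examined level by level; if it grows with
#'   concentration (heteroscedasticity, one-sided F-test) a `1/x` or
#'   `1/x^2` weighted model is adopted according to whether the growth is
#'   closer to linear or quadratic. Model order (linear vs quadratic) is
#'   decided by Mandel's fitting test backed by pure-error lack-of-fit
#'   tests. Back-calculation inverts the fitted curve and rescales to
#'   ng/mL.
NULL

WEIGHTINGS <- c("none", "1/x", "1/x^2")

# Weight vector for a weighting scheme at concentration ratios x.
weight_for <- function(weighting, x) {
  switch(match.arg(weighting, WEIGHTINGS),
         "none" = rep(1, length(x)),
         "1/x" = 1 / x,
         "1/x^2" = 1 / x^2)
}

# Derive (x, y) calibration coordinates from measurement records.
records_xy <- function(records, is_concentration) {
  if (any(records$area_is <= 0)) stop("IS peak areas must be > 0")
  data.frame(x = records$level_ng_ml / is_concentration,
             y = records$area_analyte / records$area_is,
             day = records$day, curve = records$curve,
             level = records$level_ng_ml)
}

#' Assess replicate variance across calibration levels
#'
#' Pools replicates per level and tests whether variance increases with
#' concentration: a one-sided F-test of the highest-level against the
#' lowest-level replicate variance. If heteroscedastic, the variance power
#' k is estimated as the slope of a (df-weighted) regression of
#' `log(variance)` on `log(x)` and mapped to a weighting: estimates below
#' 1.5 select `1/x`, 1.5 and above select `1/x^2`.
#'
#' @param records calibrator measurement records (>= 3 levels, >= 2
#'   replicates per level).
#' @param is_concentration IS concentration (ng/mL) defining the ratio axis.
#' @param alpha significance level of the heteroscedasticity F-test.
#' @return a `variance_assessment` list: `per_level_variance` (x, n, s2),
#'   `heteroscedastic`, `p_value`, `variance_power_estimate`,
#'   `chosen_weighting`.
#' @export
assess_variance <- function(records, is_concentration = 20, alpha = 0.05) {
  xy <- records_xy(records, is_concentration)
  levels_x <- sort(unique(xy$x))
  if (length(levels_x) < 3) stop("need >= 3 concentration levels")
  n <- tapply(xy$y, xy$x, length)[as.character(levels_x)]
  if (any(n < 2)) stop("each level needs >= 2 replicates")
  s2 <- tapply(xy$y, xy$x, stats::var)[as.character(levels_x)]

  per_level <- data.frame(x = levels_x, n = as.integer(n), s2 = as.numeric(s2))

  if (all(s2 == 0)) {
    warning("zero variance at every level; treating as homoscedastic")
    return(structure(list(per_level_variance = per_level,
                          heteroscedastic = FALSE, p_value = 1,
                          variance_power_estimate = 0,
                          chosen_weighting = "none"),
                     class = "variance_assessment"))
  }

  lo <- 1L; hi <- length(levels_x)
  f <- per_level$s2[hi] / per_level$s2[lo]
  p <- stats::pf(f, per_level$n[hi] - 1, per_level$n[lo] - 1,
                 lower.tail = FALSE)
  het <- is.finite(p) && p < alpha

  keep <- per_level$s2 > 0
  fit <- stats::lm(log(s2) ~ log(x), data = per_level[keep, ],
                   weights = per_level$n[keep] - 1)
  k_hat <- unname(stats::coef(fit)["log(x)"])

  weighting <- if (!het) "none" else if (k_hat < 1.5) "1/x" else "1/x^2"

  structure(list(per_level_variance = per_level, heteroscedastic = het,
                 p_value = unname(p), variance_power_estimate = k_hat,
                 chosen_weighting = weighting),
            class = "variance_assessment")
}

#' Construct a calibration model from known coefficients
#'
#' Used both by [fit_calibration()] and to wrap published curve
#' coefficients (e.g. from a validated method's report) for
#' back-calculation.
#'
#' @param a0,a1,a2 intercept, linear and quadratic coefficients on the
#'   (concentration ratio, response ratio) scale; `a2 = 0` means linear.
#' @param weighting one of `"none"`, `"1/x"`, `"1/x^2"`.
#' @param is_concentration IS concentration in ng/mL.
#' @param range_ng_ml calibration range (low, high) in ng/mL.
#' @param analyte_id optional label.
#' @param sigma weighted residual sd (NA when constructed from
#'   coefficients only).
#' @param n number of calibration points behind the fit.
#' @param diagnostics optional model-order diagnostics list.
#' @return a `calibration_model`.
#' @export
calibration_model <- function(a0, a1, a2 = 0, weighting = "1/x^2",
                              is_concentration = 20,
                              range_ng_ml = c(2, 100), analyte_id = NA,
                              sigma = NA_real_, n = NA_integer_,
                              diagnostics = NULL) {
  order <- if (a2 != 0) "quadratic" else "linear"
  structure(list(analyte_id = analyte_id, order = order,
                 weighting = match.arg(weighting, WEIGHTINGS),
                 coefficients = c(a0 = a0, a1 = a1, a2 = a2),
                 sigma = sigma, n = n, diagnostics = diagnostics,
                 range_ng_ml = range_ng_ml,
                 is_concentration = is_concentration),
            class = "calibration_model")
}

#' Fit a weighted calibration curve
#'
#' Weighted least squares of the response ratio on the concentration
#' ratio, with weights 1, `1/x`, or `1/x^2`.
#'
#' @param records calibrator measurement records.
#' @param weighting one of `"none"`, `"1/x"`, `"1/x^2"`.
#' @param order `"linear"` or `"quadratic"`.
#' @param is_concentration IS concentration (ng/mL).
#' @param analyte_id optional label stored in the model.
#' @return a `calibration_model`; `sigma` is the weighted residual sd
#'   `sqrt(sum(w e^2) / (n - p))`.
#' @export
fit_calibration <- function(records, weighting = "1/x^2",
                            order = c("linear", "quadratic"),
                            is_concentration = 20, analyte_id = NA) {
  order <- match.arg(order)
  xy <- records_xy(records, is_concentration)
  p <- if (order == "linear") 2L else 3L
  if (length(unique(xy$x)) < p) {
    stop("need at least ", p, " distinct levels for a ", order, " fit")
  }
  w <- weight_for(weighting, xy$x)
  fml <- if (order == "linear") y ~ x else y ~ x + I(x^2)
  fit <- stats::lm(fml, data = xy, weights = w)
  cf <- stats::coef(fit)
  a0 <- unname(cf["(Intercept)"])
  a1 <- unname(cf["x"])
  a2 <- if (order == "quadratic") unname(cf["I(x^2)"]) else 0
  sigma <- sqrt(sum(w * stats::residuals(fit)^2) / (nrow(xy) - p))
  calibration_model(a0 = a0, a1 = a1, a2 = a2, weighting = weighting,
                    is_concentration = is_concentration,
                    range_ng_ml = range(xy$level), analyte_id = analyte_id,
                    sigma = sigma, n = nrow(xy))
}

#' Predict the response ratio at given concentration ratios
#'
#' @param object a `calibration_model`.
#' @param x concentration ratios.
#' @param ... unused.
#' @return predicted response ratios.
#' @export
predict.calibration_model <- function(object, x, ...) {
  cf <- object$coefficients
  cf["a2"] * x^2 + cf["a1"] * x + cf["a0"]
}

#' @export
print.calibration_model <- function(x, ...) {
  cf <- x$coefficients
  eq <- if (x$order == "quadratic") {
    sprintf("y = %.4gx^2 %+.4gx %+.4g", cf["a2"], cf["a1"], cf["a0"])
  } else {
    sprintf("y = %.4gx %+.4g", cf["a1"], cf["a0"])
  }
  cat(sprintf("<calibration_model %s: %s, %s, weighting %s>\n",
              x$analyte_id, eq, x$order, x$weighting))
  invisible(x)
}

#' Select calibration model order (linear vs quadratic)
#'
#' Fits both orders under the given weighting and applies Mandel's fitting
#' test (F statistic from the reduction in weighted residual sum of
#' squares when the quadratic term is added, on 1 and n-3 df) together
#' with pure-error lack-of-fit F-tests of each order. The quadratic model
#' is selected iff the Mandel test is significant, or the linear fit shows
#' significant lack of fit while the quadratic does not.
#'
#' @param records calibrator records with replicated levels (>= 6 levels).
#' @param weighting weighting scheme used for both fits.
#' @param is_concentration IS concentration (ng/mL).
#' @param alpha_mandel Mandel test level (ISO 8466 convention 0.01).
#' @param alpha_lof lack-of-fit test level.
#' @return list: `order`, `mandel` (F, threshold, p), `lack_of_fit`
#'   (per-order F and p, or NULL when replication is insufficient).
#' @export
select_model_order <- function(records, weighting = "1/x^2",
                               is_concentration = 20, alpha_mandel = 0.01,
                               alpha_lof = 0.05) {
  xy <- records_xy(records, is_concentration)
  n <- nrow(xy)
  levels_x <- unique(xy$x)
  if (length(levels_x) < 4) stop("need >= 4 distinct levels")
  w <- weight_for(weighting, xy$x)

  rss_w <- function(order) {
    fml <- if (order == "linear") y ~ x else y ~ x + I(x^2)
    fit <- stats::lm(fml, data = xy, weights = w)
    sum(w * stats::residuals(fit)^2)
  }
  rss_lin <- rss_w("linear")
  rss_quad <- rss_w("quadratic")

  mandel_f <- (rss_lin - rss_quad) / (rss_quad / (n - 3))
  mandel_threshold <- stats::qf(1 - alpha_mandel, 1, n - 3)
  mandel_p <- stats::pf(mandel_f, 1, n - 3, lower.tail = FALSE)

  # Weighted pure error pooled over replicated levels.
  reps_per_level <- table(xy$x)
  has_pure_error <- any(reps_per_level >= 2)
  lof <- NULL
  if (has_pure_error) {
    ybar <- stats::ave(xy$y, xy$x)
    sspe <- sum(w * (xy$y - ybar)^2)
    df_pe <- n - length(levels_x)
    lof_one <- function(rss, p) {
      df_lof <- length(levels_x) - p
      if (df_lof <= 0 || df_pe <= 0 || sspe <= 0) return(NULL)
      f <- ((rss - sspe) / df_lof) / (sspe / df_pe)
      list(f = f, df = c(df_lof, df_pe),
           p = stats::pf(f, df_lof, df_pe, lower.tail = FALSE))
    }
    lof <- list(linear = lof_one(rss_lin, 2), quadratic = lof_one(rss_quad, 3))
  } else {
    warning("no replicated levels: lack-of-fit skipped, Mandel test decides")
  }

  mandel_significant <- is.finite(mandel_f) && mandel_f > mandel_threshold
  lof_prefers_quadratic <- !is.null(lof) && !is.null(lof$linear) &&
    !is.null(lof$quadratic) &&
    lof$linear$p < alpha_lof && lof$quadratic$p >= alpha_lof
  order <- if (mandel_significant || lof_prefers_quadratic) "quadratic"
           else "linear"

  list(order = order,
       mandel = list(f = mandel_f, threshold = mandel_threshold,
                     p = mandel_p),
       lack_of_fit = lof)
}

#' Back-calculate a concentration from a response ratio
#'
#' Inverts the calibration function on the concentration-ratio scale and
#' multiplies by the IS concentration. For quadratic models the root on
#' the monotone branch covering the calibration range is chosen (the root
#' below the parabola's vertex when `a2 < 0`, above it when `a2 > 0`);
#' ties are broken toward the range midpoint.
#'
#' @param model a `calibration_model`.
#' @param y response ratio(s), >= 0.
#' @return concentration(s) in ng/mL. Values whose root is not real or
#'   falls outside `[0, 2 x upper range]` are returned as `NA` (flagged
#'   non-quantifiable).
#' @examples
#' m <- calibration_model(a0 = 0.0579, a1 = 0.8092)
#' back_calculate(m, 0.4625)  # 10 ng/mL
#' @export
back_calculate <- function(model, y) {
  stopifnot(inherits(model, "calibration_model"))
  cf <- model$coefficients
  xmax <- model$range_ng_ml[2] / model$is_concentration
  vapply(y, function(yi) {
    if (is.na(yi) || yi < 0) return(NA_real_)
    x <- invert_one(cf, yi, xmax)
    if (is.na(x)) NA_real_ else x * model$is_concentration
  }, numeric(1))
}

invert_one <- function(cf, y, xmax) {
  a2 <- cf[["a2"]]; a1 <- cf[["a1"]]; a0 <- cf[["a0"]]
  if (a2 == 0) {
    if (a1 <= 0) stop("non-positive slope: calibration cannot be inverted")
    x <- (y - a0) / a1
    if (x < 0 && x > -1e-9) x <- 0
    if (x < 0 || x > 2 * xmax) return(NA_real_)
    return(x)
  }
  disc <- a1^2 - 4 * a2 * (a0 - y)
  if (disc < 0) return(NA_real_)
  roots <- (-a1 + c(-1, 1) * sqrt(disc)) / (2 * a2)
  # ascending branch over the calibration range: dy/dx = 2 a2 x + a1 > 0
  ascending <- 2 * a2 * roots + a1 > 0
  candidates <- roots[ascending & roots >= -1e-9 & roots <= 2 * xmax]
  if (length(candidates) == 0) {
    candidates <- roots[roots >= -1e-9 & roots <= 2 * xmax]
  }
  if (length(candidates) == 0) return(NA_real_)
  mid <- xmax / 2
  max(candidates[which.min(abs(candidates - mid))], 0)
}
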
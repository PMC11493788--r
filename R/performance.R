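#' @title Cyclic accuracy and precision
#' @name performance
#' @description Intra- and inter-day accuracy are obtained by cyclic
#'   back-calculation: within each working day, the calibration model is
#'   rebuilt from all curves but one and the held-out curve's levels are
#'   back-calculated (intra-day); across days, the model is rebuilt from
#'   all days but one and the held-out day is back-calculated (inter-day).
#'   Bias% per level is averaged over the folds. Precision is the CV of
#'   back-calculated concentrations, within days (intra) or across all
#'   replicates (inter). Acceptance: |bias| within +/- 20% at every level
#'   and CV strictly below 20%.
NULL

fold_bias <- function(train, test, weighting, order, is_concentration) {
  model <- fit_calibration(train, weighting = weighting, order = order,
                           is_concentration = is_concentration)
  y <- test$area_analyte / test$area_is
  conc <- back_calculate(model, y)
  data.frame(level = test$level_ng_ml,
             bias_pct = 100 * (conc - test$level_ng_ml) / test$level_ng_ml)
}

#' Intra-day accuracy by cyclic back-calculation
#'
#' @param records calibrator records spanning >= 2 curves per day.
#' @param weighting,order calibration form, fixed before the cyclic
#'   procedure (selection is not redone per fold).
#' @param is_concentration IS concentration (ng/mL).
#' @return list: `per_level` data.frame (level, bias_pct averaged over all
#'   folds of all days), `per_fold` detail (day, curve, level, bias_pct).
#' @export
intra_day_accuracy <- function(records, weighting = "1/x^2",
                               order = "linear", is_concentration = 20) {
  folds <- list()
  for (d in unique(records$day)) {
    day_rec <- records[records$day == d, ]
    curves <- unique(day_rec$curve)
    if (length(curves) < 2) stop("day ", d, " has < 2 curves")
    for (cv in curves) {
      b <- fold_bias(day_rec[day_rec$curve != cv, ],
                     day_rec[day_rec$curve == cv, ],
                     weighting, order, is_concentration)
      folds[[length(folds) + 1]] <- cbind(day = d, curve = cv, b)
    }
  }
  per_fold <- do.call(rbind, folds)
  per_level <- stats::aggregate(bias_pct ~ level, per_fold, mean)
  list(per_level = per_level, per_fold = per_fold)
}

#' Inter-day accuracy by cyclic back-calculation
#'
#' @inheritParams intra_day_accuracy
#' @return list as in [intra_day_accuracy()], with `day` identifying the
#'   held-out day of each fold.
#' @export
inter_day_accuracy <- function(records, weighting = "1/x^2",
                               order = "linear", is_concentration = 20) {
  days <- unique(records$day)
  if (length(days) < 3) stop("need >= 3 days for inter-day accuracy")
  folds <- lapply(days, function(d) {
    b <- fold_bias(records[records$day != d, ], records[records$day == d, ],
                   weighting, order, is_concentration)
    cbind(day = d, curve = NA, b)
  })
  per_fold <- do.call(rbind, folds)
  per_level <- stats::aggregate(bias_pct ~ level, per_fold, mean)
  list(per_level = per_level, per_fold = per_fold)
}

#' Intra- or inter-day precision (CV%)
#'
#' CV of back-calculated concentrations (default) or of raw response
#' ratios. Intra-day: CV computed within each day at each level, then
#' averaged over days. Inter-day: CV over all replicates of all days at
#' each level.
#'
#' @param records calibrator records.
#' @param mode `"intra"` or `"inter"`.
#' @param model calibration model used for back-calculation; by default a
#'   model of the given `weighting`/`order` fitted to all records.
#' @param weighting,order used when `model` is NULL.
#' @param is_concentration IS concentration (ng/mL).
#' @param scale `"concentration"` (back-calculated, default) or `"ratio"`.
#' @return data.frame: level, cv_pct.
#' @export
precision_cv <- function(records, mode = c("intra", "inter"), model = NULL,
                         weighting = "1/x^2", order = "linear",
                         is_concentration = 20,
                         scale = c("concentration", "ratio")) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  y <- records$area_analyte / records$area_is
  if (scale == "concentration") {
    if (is.null(model)) {
      model <- fit_calibration(records, weighting = weighting, order = order,
                               is_concentration = is_concentration)
    }
    value <- back_calculate(model, y)
  } else {
    value <- y
  }
  cv_of <- function(v) {
    m <- mean(v)
    if (m == 0) stop("zero mean: CV undefined")
    100 * stats::sd(v) / m
  }
  levels_u <- sort(unique(records$level_ng_ml))
  cv <- vapply(levels_u, function(l) {
    sel <- records$level_ng_ml == l
    if (mode == "inter") {
      cv_of(value[sel])
    } else {
      mean(vapply(unique(records$day[sel]), function(d) {
        v <- value[sel & records$day == d]
        if (length(v) < 2) stop("need >= 2 replicates per day per level")
        cv_of(v)
      }, numeric(1)))
    }
  }, numeric(1))
  data.frame(level = levels_u, cv_pct = cv)
}

#' Full accuracy/precision report for one analyte
#'
#' Runs the cyclic intra-/inter-day accuracy and precision procedures and
#' assembles the per-level table used for acceptance evaluation and LOQ
#' assignment.
#'
#' @inheritParams intra_day_accuracy
#' @return an `accuracy_precision_report`: per-level data.frame with
#'   `bias_intra`, `bias_inter`, `cv_intra`, `cv_inter` plus analyte-level
#'   means.
#' @export
accuracy_precision_report <- function(records, weighting = "1/x^2",
                                      order = "linear",
                                      is_concentration = 20) {
  acc_intra <- intra_day_accuracy(records, weighting, order, is_concentration)
  acc_inter <- inter_day_accuracy(records, weighting, order, is_concentration)
  prec_intra <- precision_cv(records, "intra", weighting = weighting,
                             order = order,
                             is_concentration = is_concentration)
  prec_inter <- precision_cv(records, "inter", weighting = weighting,
                             order = order,
                             is_concentration = is_concentration)
  tab <- data.frame(level = acc_intra$per_level$level,
                    bias_intra = acc_intra$per_level$bias_pct,
                    bias_inter = acc_inter$per_level$bias_pct,
                    cv_intra = prec_intra$cv_pct,
                    cv_inter = prec_inter$cv_pct)
  structure(list(per_level = tab,
                 mean_bias_intra = mean(tab$bias_intra),
                 mean_bias_inter = mean(tab$bias_inter),
                 mean_cv_intra = mean(tab$cv_intra),
                 mean_cv_inter = mean(tab$cv_inter)),
            class = "accuracy_precision_report")
}

#' Evaluate accuracy/precision acceptance criteria
#'
#' Boundary semantics follow the validation wording: |bias| equal to the
#' limit passes ("within the +/- 20% range"); CV equal to the limit fails
#' ("below 20%").
#'
#' @param report an [accuracy_precision_report()].
#' @param bias_limit bias acceptance half-width, percent.
#' @param cv_limit CV acceptance bound, percent.
#' @return list: `pass` (logical), `reasons` (character, empty when
#'   passing, otherwise naming each failing level and criterion).
#' @export
evaluate_acceptance <- function(report, bias_limit = 20, cv_limit = 20) {
  tab <- report$per_level
  reasons <- character()
  for (i in seq_len(nrow(tab))) {
    for (col in c("bias_intra", "bias_inter")) {
      if (abs(tab[[col]][i]) > bias_limit) {
        reasons <- c(reasons, sprintf("%s at level %g ng/mL: %.1f%% (|bias| > %g%%)",
                                      col, tab$level[i], tab[[col]][i],
                                      bias_limit))
      }
    }
    for (col in c("cv_intra", "cv_inter")) {
      if (tab[[col]][i] >= cv_limit) {
        reasons <- c(reasons, sprintf("%s at level %g ng/mL: %.1f%% (CV >= %g%%)",
                                      col, tab$level[i], tab[[col]][i],
                                      cv_limit))
      }
    }
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}
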
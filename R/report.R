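#' @title End-to-end validation run and reporting
#' @name report
#' @description Ties the pipeline together for a whole panel: per analyte,
#'   variance assessment, model-order selection, weighted fit, Hubaux-Vos
#'   LOD, cyclic accuracy/precision with LOQ assignment, matrix
#'   effect / recovery / process efficiency and stability ANOVA where the
#'   corresponding records are present. Per-analyte errors are isolated:
#'   a failing analyte is reported as errored without aborting the rest.
NULL

default_validation_config <- function() {
  list(is_concentration = 20, alpha_het = 0.05, alpha_mandel = 0.01,
       alpha_lof = 0.05, alpha_lod = 0.05, beta_lod = 0.05,
       alpha_stability = 0.05, bias_limit = 20, cv_limit = 20)
}

#' Read a validation configuration (YAML or JSON)
#'
#' Unspecified entries fall back to the package defaults (IS 20 ng/mL,
#' heteroscedasticity / lack-of-fit / stability alpha 0.05, Mandel alpha
#' 0.01, Hubaux-Vos alpha = beta = 0.05, bias limit 20%, CV limit 20%).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or NULL for the
#'   defaults.
#' @return named configuration list.
#' @export
load_validation_config <- function(path = NULL) {
  config <- default_validation_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
            else jsonlite::read_json(path, simplifyVector = TRUE)
    config[names(user)] <- user
  }
  config
}

validate_one_analyte <- function(records, analyte_id, config) {
  cal <- records[records$role == "calibrator" &
                   records$analyte_id == analyte_id, ]
  if (nrow(cal) == 0) stop("no calibrator records")
  isc <- config$is_concentration

  va <- assess_variance(cal, isc, alpha = config$alpha_het)
  sel <- select_model_order(cal, va$chosen_weighting, isc,
                            alpha_mandel = config$alpha_mandel,
                            alpha_lof = config$alpha_lof)
  model <- fit_calibration(cal, va$chosen_weighting, sel$order, isc,
                           analyte_id = analyte_id)
  lod <- hubaux_vos_lod(cal, va$chosen_weighting, config$alpha_lod,
                        config$beta_lod, isc)
  perf <- accuracy_precision_report(cal, va$chosen_weighting, sel$order, isc)
  acceptance <- evaluate_acceptance(perf, config$bias_limit, config$cv_limit)
  tab <- perf$per_level
  loq <- assign_loq(rep(tab$level, 2),
                    c(tab$bias_intra, tab$bias_inter),
                    c(tab$cv_intra, tab$cv_inter),
                    config$bias_limit, config$cv_limit)

  out <- list(analyte_id = analyte_id,
              variance = va,
              model = model,
              order_selection = sel,
              lod_hubaux_vos_ng_ml = lod$lod_ng_ml,
              performance = perf,
              loq_ng_ml = loq$loq_ng_ml,
              pass = acceptance$pass,
              reasons = acceptance$reasons)

  sets <- lapply(1:3, function(i) {
    records[records$role == paste0("me_set", i) &
              records$analyte_id == analyte_id, ]
  })
  if (all(vapply(sets, nrow, integer(1)) > 0)) {
    out$matrix <- matrix_effect_report(sets[[1]], sets[[2]], sets[[3]])
  }

  stab <- records[records$role == "stability" &
                    records$analyte_id == analyte_id, ]
  if (nrow(stab) > 0) {
    out$stability <- stability_report(stab, alpha = config$alpha_stability)
    out$stable <- !any(out$stability$significant)
  }
  out
}

#' Run the full validation pipeline over a panel
#'
#' @param measurements measurement records data.frame (schema of
#'   [write_measurements()]) or path to such a CSV.
#' @param panel a `pfas_panel` or path to a transition CSV; analytes
#'   validated are the panel targets present in the measurements.
#' @param config configuration list from [load_validation_config()], or
#'   NULL for defaults.
#' @return a `validation_report`: per-analyte results (model, LOD, LOQ,
#'   accuracy/precision, matrix/recovery, stability, pass flag or error
#'   message) plus run metadata (config, seed echo, counts).
#' @export
run_full_validation <- function(measurements, panel, config = NULL) {
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  if (is.character(panel)) panel <- load_transition_table(panel)
  if (is.null(config)) config <- default_validation_config()

  targets <- intersect(panel_targets(panel), unique(measurements$analyte_id))
  if (length(targets) == 0) {
    stop("no panel target has measurement records")
  }
  results <- lapply(targets, function(id) {
    tryCatch(validate_one_analyte(measurements, id, config),
             error = function(e) {
               list(analyte_id = id, error = conditionMessage(e))
             })
  })
  names(results) <- targets
  errored <- vapply(results, function(r) !is.null(r$error), logical(1))
  structure(list(
    analytes = results,
    config = config,
    n_analytes = length(targets),
    n_errored = sum(errored),
    all_pass = !any(errored) &&
      all(vapply(results, function(r) isTRUE(r$pass), logical(1)))
  ), class = "validation_report")
}

report_to_list <- function(report) {
  num <- function(x) if (is.null(x)) NULL else signif(x, 6)
  lapply(report$analytes, function(r) {
    if (!is.null(r$error)) return(list(analyte_id = r$analyte_id,
                                       error = r$error))
    out <- list(
      analyte_id = r$analyte_id,
      weighting = r$variance$chosen_weighting,
      heteroscedastic = r$variance$heteroscedastic,
      variance_power = num(r$variance$variance_power_estimate),
      order = r$model$order,
      coefficients = as.list(num(r$model$coefficients)),
      lod_hubaux_vos_ng_ml = num(r$lod_hubaux_vos_ng_ml),
      loq_ng_ml = num(r$loq_ng_ml),
      accuracy_precision = lapply(as.list(r$performance$per_level), num),
      pass = r$pass)
    if (!is.null(r$matrix)) {
      out$matrix_effect <- list(me_pct = num(r$matrix$me$mean_pct),
                                er_pct = num(r$matrix$er$mean_pct),
                                pe_pct = num(r$matrix$pe_pct),
                                ie_pct = num(r$matrix$ie_pct),
                                classification = r$matrix$classification)
    }
    if (!is.null(r$stability)) {
      out$stability <- lapply(as.list(r$stability), function(col) {
        if (is.numeric(col)) num(col) else col
      })
      out$stable <- r$stable
    }
    out
  })
}

#' Write a validation report as JSON
#'
#' Analytes appear in panel order and floats are serialized at six
#' significant digits, so identical inputs produce byte-identical output.
#'
#' @param report a `validation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  payload <- list(analytes = report_to_list(report),
                  config = report$config,
                  n_analytes = report$n_analytes,
                  n_errored = report$n_errored,
                  all_pass = report$all_pass)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Validate a written JSON report against the shipped schema
#'
#' Light structural validation: checks the required keys and basic types
#' declared in `extdata/report_schema.json` (no external schema engine is
#' used).
#'
#' @param path path to a JSON report written by [write_report_json()].
#' @return TRUE invisibly; errors describe the first violation found.
#' @export
validate_report_json <- function(path) {
  schema <- jsonlite::read_json(pfasval_example("report_schema.json"))
  doc <- jsonlite::read_json(path)
  for (key in unlist(schema$required)) {
    if (is.null(doc[[key]])) stop("report missing required key: ", key)
  }
  if (!is.logical(doc$all_pass)) stop("all_pass must be boolean")
  if (doc$n_analytes != length(doc$analytes)) {
    stop("n_analytes disagrees with the analytes object")
  }
  req_analyte <- unlist(
    schema$properties$analytes$additionalProperties$required)
  for (a in doc$analytes) {
    for (key in req_analyte) {
      if (is.null(a[[key]])) stop("analyte entry missing key: ", key)
    }
    if (is.null(a$error) && !is.logical(a$pass)) {
      stop("non-errored analyte ", a$analyte_id, " lacks a logical pass flag")
    }
  }
  invisible(TRUE)
}

#' Write a human-readable markdown validation report
#'
#' @param report a `validation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_md <- function(report, path) {
  lines <- c("# Validation report", "",
             sprintf("Analytes: %d (errored: %d). Overall pass: %s.",
                     report$n_analytes, report$n_errored, report$all_pass),
             "",
             "| analyte | weighting | order | LOD (ng/mL) | LOQ (ng/mL) | ME% | ER% | PE% | stable | pass |",
             "|---|---|---|---|---|---|---|---|---|---|")
  fmt <- function(x, d = 2) if (is.null(x) || length(x) == 0 || is.na(x)) "-"
                            else formatC(x, digits = d, format = "f")
  for (r in report$analytes) {
    if (!is.null(r$error)) {
      lines <- c(lines, sprintf("| %s | ERROR: %s |||||||||", r$analyte_id,
                                r$error))
      next
    }
    me <- if (is.null(r$matrix)) NULL else r$matrix$me$mean_pct
    er <- if (is.null(r$matrix)) NULL else r$matrix$er$mean_pct
    pe <- if (is.null(r$matrix)) NULL else r$matrix$pe_pct
    stable <- if (is.null(r$stable)) "not assessed" else as.character(r$stable)
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %s | %s | %s | %s | %s | %s |",
      r$analyte_id, r$variance$chosen_weighting, r$model$order,
      fmt(r$lod_hubaux_vos_ng_ml), fmt(r$loq_ng_ml, 0),
      fmt(me, 0), fmt(er, 0), fmt(pe, 0), stable, r$pass))
  }
  writeLines(lines, path)
  invisible(path)
}
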
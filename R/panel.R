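#' @title Analytical panel: SRM transitions, internal standards, gradient,
#'   spiking arithmetic
#' @name panel
#' @description Functions for loading and validating the SRM (selected
#'   reaction monitoring) transition panel of a targeted LC-MS/MS assay,
#'   resolving analyte-to-internal-standard assignments, and small pieces
#'   of acquisition arithmetic (gradient run time, spike concentrations).
#'
#'   A panel is stored in long format: one row per (analyte, product ion),
#'   with an `ordinal` column ordering the transitions of each analyte.
#'   The transition with `ordinal == 1` is the quantifier.
NULL

PANEL_COLUMNS <- c("analyte_id", "name", "family", "rt_min", "precursor_mz",
                   "product_mz", "ce_v", "cxp_v", "ordinal",
                   "internal_standard_id")

PANEL_FAMILIES <- c("perfluorocarboxylic acid", "perfluorosulfonic acid",
                    "replacement PFAS", "perfluoroalkylether",
                    "internal standard")

#' Load an SRM transition table
#'
#' Reads a long-format transition CSV (one row per analyte/product-ion pair)
#' and validates it into a `pfas_panel` object. The quantifier transition of
#' each analyte is the row with `ordinal == 1`; internal standards (family
#' `"internal standard"`) carry a single transition and an empty
#' `internal_standard_id`.
#'
#' @param path path to a CSV file with columns
#'   `analyte_id,name,family,rt_min,precursor_mz,product_mz,ce_v,cxp_v,ordinal,internal_standard_id`.
#' @return A `pfas_panel`: a data.frame of transitions with one attribute,
#'   `analytes`, a per-analyte summary data.frame.
#' @examples
#' panel <- load_transition_table(pfasval_example("transitions.csv"))
#' nrow(panel_analytes(panel))  # 34 entries: 25 targets + 9 IS
#' @export
load_transition_table <- function(path) {
  if (!file.exists(path)) stop("transition table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(internal_standard_id = "character"))
  missing_cols <- setdiff(PANEL_COLUMNS, names(tab))
  if (length(missing_cols) > 0) {
    stop("transition table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- tab[PANEL_COLUMNS]
  if (nrow(tab) == 0) stop("transition table has no rows (empty panel)")
  as_pfas_panel(tab)
}

#' Construct and validate a panel from a transition data.frame
#'
#' @param tab long-format transition data.frame (see
#'   [load_transition_table()] for the schema).
#' @return validated `pfas_panel`.
#' @export
as_pfas_panel <- function(tab) {
  tab$internal_standard_id[is.na(tab$internal_standard_id)] <- ""
  dup <- duplicated(tab[c("analyte_id", "ordinal")])
  if (any(dup)) {
    stop("duplicate (analyte_id, ordinal) row(s): ",
         paste(unique(tab$analyte_id[dup]), collapse = ", "))
  }
  if (any(tab$rt_min <= 0)) stop("retention times must be > 0")
  if (any(tab$precursor_mz <= 0) || any(tab$product_mz <= 0)) {
    stop("m/z values must be > 0")
  }
  if (any(tab$ce_v >= 0) || any(tab$cxp_v >= 0)) {
    stop("collision parameters (CE, CXP) must be negative (negative-mode ESI)")
  }
  bad_family <- setdiff(unique(tab$family), PANEL_FAMILIES)
  if (length(bad_family) > 0) {
    stop("unknown analyte family: ", paste(bad_family, collapse = ", "))
  }

  ids <- unique(tab$analyte_id)
  quantifiers <- tapply(tab$ordinal, tab$analyte_id, function(o) sum(o == 1))
  if (any(quantifiers != 1)) {
    stop("each analyte needs exactly one quantifier (ordinal 1); offending: ",
         paste(names(quantifiers)[quantifiers != 1], collapse = ", "))
  }

  is_is <- tab$family == "internal standard"
  is_ids <- unique(tab$analyte_id[is_is])
  target_rows <- tab[!is_is, ]
  dangling <- setdiff(unique(target_rows$internal_standard_id), c(is_ids, ""))
  if (length(dangling) > 0) {
    stop("internal_standard_id does not resolve to an IS entry: ",
         paste(dangling, collapse = ", "))
  }
  no_is <- unique(target_rows$analyte_id[target_rows$internal_standard_id == ""])
  if (length(no_is) > 0) {
    stop("target analyte(s) without an internal standard: ",
         paste(no_is, collapse = ", "))
  }
  n_is_per_analyte <- tapply(target_rows$internal_standard_id,
                             target_rows$analyte_id,
                             function(x) length(unique(x)))
  if (any(n_is_per_analyte != 1)) {
    stop("conflicting internal standard assignments for: ",
         paste(names(n_is_per_analyte)[n_is_per_analyte != 1], collapse = ", "))
  }
  n_trans_is <- table(tab$analyte_id[is_is])
  if (any(n_trans_is != 1)) {
    stop("internal standards must carry exactly one transition; offending: ",
         paste(names(n_trans_is)[n_trans_is != 1], collapse = ", "))
  }

  first <- tab[tab$ordinal == 1, ]
  analytes <- data.frame(
    analyte_id = first$analyte_id,
    name = first$name,
    family = first$family,
    rt_min = first$rt_min,
    n_transitions = as.integer(table(tab$analyte_id)[first$analyte_id]),
    quantifier_product_mz = first$product_mz,
    internal_standard_id = first$internal_standard_id,
    is_internal_standard = first$family == "internal standard",
    stringsAsFactors = FALSE
  )
  rownames(analytes) <- NULL

  structure(tab, class = c("pfas_panel", "data.frame"), analytes = analytes)
}

#' Per-analyte summary of a panel
#'
#' @param panel a `pfas_panel`.
#' @return data.frame with one row per analyte: family, retention time,
#'   transition count, quantifier product ion, and IS assignment.
#' @export
panel_analytes <- function(panel) {
  stopifnot(inherits(panel, "pfas_panel"))
  attr(panel, "analytes")
}

#' Target (non internal standard) analyte ids of a panel
#' @param panel a `pfas_panel`.
#' @return character vector of target analyte ids, in panel order.
#' @export
panel_targets <- function(panel) {
  a <- panel_analytes(panel)
  a$analyte_id[!a$is_internal_standard]
}

#' Internal standard ids of a panel
#' @param panel a `pfas_panel`.
#' @return character vector of IS ids.
#' @export
panel_internal_standards <- function(panel) {
  a <- panel_analytes(panel)
  a$analyte_id[a$is_internal_standard]
}

#' Write a panel back to CSV
#'
#' Inverse of [load_transition_table()]: the written file reproduces the
#' input field-for-field.
#'
#' @param panel a `pfas_panel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_transition_table <- function(panel, path) {
  stopifnot(inherits(panel, "pfas_panel"))
  out <- as.data.frame(panel)[PANEL_COLUMNS]
  utils::write.csv(out, path, row.names = FALSE, quote = which(
    vapply(out, is.character, logical(1))))
  invisible(path)
}

#' Resolve the internal standard assigned to a target analyte
#'
#' @param analyte_id a target analyte id present in the panel.
#' @param panel a `pfas_panel`.
#' @return the IS analyte id (character scalar).
#' @examples
#' panel <- load_transition_table(pfasval_example("transitions.csv"))
#' map_internal_standard("PFTrDA", panel)  # "MPFDoA"
#' @export
map_internal_standard <- function(analyte_id, panel) {
  a <- panel_analytes(panel)
  row <- a[a$analyte_id == analyte_id, ]
  if (nrow(row) == 0) stop("unknown analyte: ", analyte_id)
  if (row$is_internal_standard) {
    stop(analyte_id, " is itself an internal standard and has no IS")
  }
  row$internal_standard_id
}

#' @describeIn panel_analytes path to a packaged example data file.
#' @param file file name under the package's `extdata` directory.
#' @export
pfasval_example <- function(file) {
  path <- system.file("extdata", file, package = "pfasval")
  if (path == "") stop("no packaged file named ", file)
  path
}

# ---- gradient program -------------------------------------------------------

#' Build an LC gradient program
#'
#' @param duration_min segment durations in minutes.
#' @param pct_b_end mobile-phase %B at each segment end (A + B = 100).
#' @param mode per-segment mode, `"isocratic"` or `"linear"`.
#' @param flow_ml_min flow rate in mL/min.
#' @return a `gradient_program` object.
#' @export
gradient_program <- function(duration_min, pct_b_end, mode,
                             flow_ml_min = 0.5) {
  n <- length(duration_min)
  stopifnot(length(pct_b_end) == n, length(mode) == n)
  if (any(duration_min <= 0)) stop("segment durations must be > 0")
  if (any(pct_b_end < 0 | pct_b_end > 100)) {
    stop("mobile-phase compositions must lie in [0, 100]")
  }
  if (!all(mode %in% c("isocratic", "linear"))) {
    stop("segment mode must be 'isocratic' or 'linear'")
  }
  if (flow_ml_min <= 0) stop("flow rate must be > 0")
  structure(list(
    segments = data.frame(duration_min = duration_min,
                          pct_b_end = pct_b_end, mode = mode,
                          stringsAsFactors = FALSE),
    flow_ml_min = flow_ml_min
  ), class = "gradient_program")
}

#' Read a gradient program from YAML
#'
#' @param path YAML file with `flow_ml_min` and a `segments` list of
#'   `{duration_min, pct_b_end, mode}` entries.
#' @return a `gradient_program`.
#' @export
load_gradient <- function(path) {
  g <- yaml::read_yaml(path)
  seg <- do.call(rbind, lapply(g$segments, as.data.frame))
  gradient_program(seg$duration_min, seg$pct_b_end, as.character(seg$mode),
                   flow_ml_min = g$flow_ml_min)
}

#' Total run time of a gradient program
#'
#' @param program a `gradient_program`, or `NULL`/empty for a zero-length run.
#' @return total run time in minutes (sum of segment durations).
#' @examples
#' g <- gradient_program(c(0.5, 9.5, 2, 1), c(25, 95, 95, 25),
#'                       c("isocratic", "linear", "isocratic", "linear"))
#' gradient_runtime(g)  # 13
#' @export
gradient_runtime <- function(program) {
  if (is.null(program)) return(0)
  stopifnot(inherits(program, "gradient_program"))
  if (nrow(program$segments) == 0) return(0)
  sum(program$segments$duration_min)
}

# ---- spiking arithmetic -----------------------------------------------------

#' Define a spiking plan
#'
#' @param added_volume_ul volume of spiking solution added (microlitres).
#' @param stock_ng_ml concentration of the spiking solution (ng/mL).
#' @param reference_volume_ul the sample volume the final concentration
#'   refers to (microlitres), e.g. the 10 uL blood volume of a volumetric
#'   dried blood spot.
#' @return a `spike_plan` object.
#' @export
spike_plan <- function(added_volume_ul, stock_ng_ml, reference_volume_ul) {
  if (added_volume_ul <= 0) stop("added volume must be > 0")
  if (reference_volume_ul <= 0) stop("reference volume must be > 0")
  if (stock_ng_ml < 0) stop("stock concentration must be >= 0")
  structure(list(added_volume_ul = added_volume_ul,
                 stock_ng_ml = stock_ng_ml,
                 reference_volume_ul = reference_volume_ul),
            class = "spike_plan")
}

#' Final concentration produced by a spike
#'
#' Added mass (volume x stock concentration) divided by the reference
#' volume. Volumes cancel unit-wise, so the result is in ng/mL.
#'
#' @param plan a [spike_plan()].
#' @return concentration in ng/mL referred to the reference volume.
#' @examples
#' # 4 uL of 50 ng/mL IS onto a 10 uL blood spot -> 20 ng/mL
#' spike_final_concentration(spike_plan(4, 50, 10))
#' @export
spike_final_concentration <- function(plan) {
  stopifnot(inherits(plan, "spike_plan"))
  plan$added_volume_ul * plan$stock_ng_ml / plan$reference_volume_ul
}
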
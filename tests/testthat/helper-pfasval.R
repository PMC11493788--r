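# Shared fixtures built in code.

fixture_panel <- function() {
  load_transition_table(pfasval_example("transitions.csv"))
}

published_models <- function() {
  utils::read.csv(pfasval_example("calibration_published.csv"),
                  stringsAsFactors = FALSE)
}

published_matrix <- function() {
  utils::read.csv(pfasval_example("matrix_effect_published.csv"),
                  stringsAsFactors = FALSE)
}

# Noise-free generator config (truth curve reproduced exactly).
noise_free_config <- function(..., seed = 1L) {
  synthetic_config(..., base_cv = 0, day_effect_sd = 0, seed = seed)
}

# Calibrator records lying exactly on a published curve, replicated over
# days/curves so replicated-level machinery works.
records_on_curve <- function(a0, a1, a2 = 0, levels = c(2, 5, 10, 20, 50, 100),
                             is_conc = 20, days = 3, curves = 3) {
  grid <- expand.grid(level = levels, curve = seq_len(curves),
                      day = seq_len(days))
  x <- grid$level / is_conc
  y <- a2 * x^2 + a1 * x + a0
  data.frame(analyte_id = "FIX", role = "calibrator", day = grid$day,
             curve = grid$curve, replicate = grid$curve,
             level_ng_ml = grid$level, area_analyte = y * 1e5, area_is = 1e5)
}

# Spike-set records at fixed response ratios (exact, no noise).
set_records <- function(ratios_by_level, role, reps = 3) {
  levels <- as.numeric(names(ratios_by_level))
  grid <- expand.grid(level = levels, replicate = seq_len(reps))
  y <- ratios_by_level[as.character(grid$level)]
  data.frame(analyte_id = "FIX", role = role, day = 1, curve = 1,
             replicate = grid$replicate, level_ng_ml = grid$level,
             area_analyte = unname(y) * 1e5, area_is = 1e5)
}
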
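#' @title Synthetic measurement generator
#' @name synthetic
#' @description Generates every dataset shape the validation pipeline
#'   consumes — calibration curves, matrix-effect spike sets, stability
#'   grids, design-of-experiments response matrices, and Gaussian-peak
#'   chromatograms — with the statistical structure the analysis assumes:
#'   heteroscedastic noise whose variance grows as a power of
#'   concentration, multiplicative day effects, ion-enhancement and
#'   recovery multipliers, and optional exponential degradation.
#'
#'   Noise is multiplicative log-normal on the response-ratio scale so
#'   generated responses are always positive; its level is set so the
#'   absolute response sd follows `sd(y) = base_cv * truth(1) * x^(k/2)`,
#'   i.e. variance proportional to `x^k` with k = `variance_power`.
NULL

# Deterministic child seed from (seed, purpose label); keeps sub-generators
# independent while a single config seed controls everything. Kept < 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Generative configuration for synthetic validation data
#'
#' The defaults are the validation design of the assay being emulated:
#' six calibration levels 2-100 ng/mL, three curves per day on three
#' non-consecutive days (54 analyses), internal standard at 20 ng/mL,
#' variance growing quadratically with concentration (`variance_power = 2`)
#' at a base CV of 8%, and a modest multiplicative day effect.
#'
#' @param levels calibration levels, ng/mL, strictly increasing.
#' @param curves_per_day calibration curves per working session.
#' @param days number of working sessions.
#' @param is_concentration internal standard concentration, ng/mL; the
#'   concentration-ratio axis is `level / is_concentration`.
#' @param slope,intercept,quad true calibration coefficients on the
#'   (concentration ratio, response ratio) scale; `quad` nonzero gives a
#'   saturating quadratic truth.
#' @param variance_power exponent k of `var(y) ~ x^k`; canonical values
#'   0 (homoscedastic), 1, and 2.
#' @param base_cv relative response sd at x = 1 (fraction, not percent).
#' @param day_effect_sd sd (log scale, approx. fraction) of the shared
#'   multiplicative day factor.
#' @param me_multiplier ion enhancement/suppression multiplier applied to
#'   matrix-present spike sets (1.28 = +28% enhancement).
#' @param er_multiplier extraction recovery multiplier (0.93 = 93%).
#' @param seed integer master seed; all sub-generators derive child seeds
#'   from it deterministically by purpose label.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(levels = c(2, 5, 10, 20, 50, 100),
                             curves_per_day = 3,
                             days = 3,
                             is_concentration = 20,
                             slope = 1.0,
                             intercept = 0.05,
                             quad = 0,
                             variance_power = 2,
                             base_cv = 0.08,
                             day_effect_sd = 0.04,
                             me_multiplier = 1.28,
                             er_multiplier = 0.93,
                             seed = 1L) {
  if (any(diff(levels) <= 0) || any(levels <= 0)) {
    stop("levels must be strictly increasing and > 0")
  }
  if (base_cv < 0 || day_effect_sd < 0) stop("cv parameters must be >= 0")
  if (me_multiplier <= 0 || er_multiplier <= 0) {
    stop("effect multipliers must be > 0")
  }
  if (is_concentration <= 0) stop("is_concentration must be > 0")
  structure(list(levels = levels, curves_per_day = curves_per_day,
                 days = days, is_concentration = is_concentration,
                 slope = slope, intercept = intercept, quad = quad,
                 variance_power = variance_power, base_cv = base_cv,
                 day_effect_sd = day_effect_sd,
                 me_multiplier = me_multiplier,
                 er_multiplier = er_multiplier,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# True mean response ratio at concentration ratio x.
truth_curve <- function(config, x) {
  config$quad * x^2 + config$slope * x + config$intercept
}

# Relative sd at concentration ratio x implied by the absolute power law
# sd(y) = base_cv * truth(1) * x^(k/2).
relative_sd <- function(config, x) {
  config$base_cv * truth_curve(config, 1) * x^(config$variance_power / 2) /
    truth_curve(config, x)
}

# Multiplicative log-normal noise with target CV `cv`, mean 1.
lognormal_factor <- function(n, cv) {
  if (all(cv == 0)) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

new_records <- function(analyte_id, role, day, curve, replicate, level,
                        y, area_is = 1e5, ...) {
  data.frame(analyte_id = analyte_id, role = role, day = day, curve = curve,
             replicate = replicate, level_ng_ml = level,
             area_analyte = y * area_is, area_is = area_is, ...,
             stringsAsFactors = FALSE)
}

#' Generate synthetic calibration measurements
#'
#' One record per (level, curve, day). The response ratio is drawn around
#' the configured truth curve with multiplicative log-normal noise whose
#' absolute sd scales as `x^(k/2)` (variance proportional to `x^k`), times
#' a log-normal day factor shared by all records of a day.
#'
#' @param config a [synthetic_config()].
#' @param analyte_id label stamped on the records.
#' @return data.frame of measurement records with columns
#'   `analyte_id, role, day, curve, replicate, level_ng_ml, area_analyte,
#'   area_is`; `role` is `"calibrator"`. Deterministic given the config seed.
#' @examples
#' cal <- generate_calibration(synthetic_config(seed = 7))
#' nrow(cal)  # 6 levels x 3 curves x 3 days = 54
#' @export
generate_calibration <- function(config, analyte_id = "SYN1") {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, paste0("calibration:", analyte_id)))
  grid <- expand.grid(level = config$levels,
                      curve = seq_len(config$curves_per_day),
                      day = seq_len(config$days))
  day_factor <- lognormal_factor(config$days, config$day_effect_sd)
  x <- grid$level / config$is_concentration
  mu <- truth_curve(config, x)
  y <- mu * day_factor[grid$day] * lognormal_factor(nrow(grid),
                                                    relative_sd(config, x))
  new_records(analyte_id, "calibrator", grid$day, grid$curve,
              replicate = grid$curve, level = grid$level, y = y)
}

#' Generate matrix-effect / recovery spike sets
#'
#' Emulates the three-set post-extraction spike design: set 2 is the neat
#' (matrix-free) reference, set 1 multiplies it by the ion-enhancement
#' factor (spike added after extracting blank matrix), and set 3 further
#' multiplies by the recovery factor (spike added before extraction).
#'
#' @param config a [synthetic_config()].
#' @param qc_levels spike levels in ng/mL (default low/medium/high QC).
#' @param replicates replicates per level per set.
#' @param analyte_id label stamped on the records.
#' @return data.frame of records with `role` in
#'   `me_set1`, `me_set2`, `me_set3`.
#' @export
generate_me_er_sets <- function(config, qc_levels = c(2, 15, 75),
                                replicates = 3, analyte_id = "SYN1") {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, paste0("me_er:", analyte_id)))
  grid <- expand.grid(level = qc_levels, replicate = seq_len(replicates),
                      set = 1:3)
  x <- grid$level / config$is_concentration
  mult <- c(config$me_multiplier,                       # set 1: matrix, post-spike
            1,                                          # set 2: neat
            config$me_multiplier * config$er_multiplier # set 3: pre-spike
            )[grid$set]
  mu <- truth_curve(config, x) * mult
  y <- mu * lognormal_factor(nrow(grid), relative_sd(config, x))
  new_records(analyte_id, paste0("me_set", grid$set), day = 1, curve = 1,
              replicate = grid$replicate, level = grid$level, y = y)
}

#' Generate a stability study grid
#'
#' Full temperature x time x concentration grid with `reps` replicates per
#' cell. The response ratio decays exponentially at `degradation_rate`
#' (fraction per day, per temperature); the stable, assay-faithful scenario
#' is rate 0 everywhere.
#'
#' @param config a [synthetic_config()].
#' @param temps storage temperatures, degrees C.
#' @param times storage durations, days.
#' @param concs concentrations tested, ng/mL.
#' @param reps replicates per condition.
#' @param degradation_rate scalar or named-by-temperature vector of
#'   first-order loss rates (fraction/day). Decay is measured from day 1.
#' @param analyte_id label stamped on the records.
#' @return data.frame of records with `role = "stability"` and condition
#'   columns `temp_c`, `time_d`.
#' @examples
#' st <- generate_stability(synthetic_config(seed = 3))
#' nrow(st)  # 3 temps x 3 times x 2 concs x 3 reps = 54
#' @export
generate_stability <- function(config, temps = c(-20, 4, 25),
                               times = c(1, 14, 28), concs = c(2, 75),
                               reps = 3, degradation_rate = 0,
                               analyte_id = "SYN1") {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, paste0("stability:", analyte_id)))
  if (is.null(names(degradation_rate))) {
    rate <- stats::setNames(rep(degradation_rate[1], length(temps)),
                            as.character(temps))
  } else {
    rate <- stats::setNames(rep(0, length(temps)), as.character(temps))
    rate[names(degradation_rate)] <- degradation_rate
  }
  grid <- expand.grid(temp_c = temps, time_d = times, level = concs,
                      replicate = seq_len(reps))
  x <- grid$level / config$is_concentration
  decay <- exp(-rate[as.character(grid$temp_c)] * (grid$time_d - 1))
  mu <- truth_curve(config, x) * decay
  y <- mu * lognormal_factor(nrow(grid), relative_sd(config, x))
  new_records(analyte_id, "stability", day = 1, curve = 1,
              replicate = grid$replicate, level = grid$level, y = y,
              temp_c = grid$temp_c, time_d = grid$time_d)
}

#' Generate design-of-experiments responses
#'
#' Response surface on coded factors: `intercept + beta_volume * volume +
#' beta_time * time + beta_interaction * volume * time + noise`, one column
#' per analyte.
#'
#' @param design a [full_factorial()] design with coded columns
#'   `coded_volume` and `coded_time`.
#' @param analytes analyte ids (columns of the response matrix).
#' @param intercept,beta_volume,beta_time,beta_interaction effect-model
#'   coefficients; scalars are recycled across analytes.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return numeric matrix, runs x analytes, with run ids as row names.
#' @export
generate_doe_responses <- function(design, analytes = paste0("A", 1:25),
                                   intercept = 1, beta_volume = 0.05,
                                   beta_time = 0.5, beta_interaction = 0,
                                   noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(design, "factorial_design"))
  set.seed(derive_seed(seed, "doe"))
  runs <- design$runs
  p <- length(analytes)
  rec <- function(v) rep_len(v, p)
  intercept <- rec(intercept); beta_volume <- rec(beta_volume)
  beta_time <- rec(beta_time); beta_interaction <- rec(beta_interaction)
  resp <- sapply(seq_len(p), function(j) {
    intercept[j] + beta_volume[j] * runs$coded_volume +
      beta_time[j] * runs$coded_time +
      beta_interaction[j] * runs$coded_volume * runs$coded_time +
      stats::rnorm(nrow(runs), 0, noise_sd)
  })
  resp <- matrix(resp, nrow = nrow(runs),
                 dimnames = list(runs$run_id, analytes))
  resp
}

#' Chromatogram generator configuration
#'
#' @param peak_center peak apex position, minutes.
#' @param peak_sigma Gaussian peak sigma, minutes.
#' @param height_per_unit_conc peak height per ng/mL, counts.
#' @param baseline_noise_sd baseline noise sd, counts.
#' @param sampling_rate points per minute.
#' @param duration trace length, minutes; must cover the peak +/- 4 sigma.
#' @return a `chromatogram_config`.
#' @export
chromatogram_config <- function(peak_center = 5, peak_sigma = 0.05,
                                height_per_unit_conc = 1000,
                                baseline_noise_sd = 20,
                                sampling_rate = 600, duration = 10) {
  if (peak_sigma <= 0) stop("peak_sigma must be > 0")
  if (baseline_noise_sd < 0) stop("baseline_noise_sd must be >= 0")
  if (peak_center - 4 * peak_sigma < 0 ||
      peak_center + 4 * peak_sigma > duration) {
    stop("duration must cover peak_center +/- 4 sigma")
  }
  structure(as.list(environment()), class = "chromatogram_config")
}

#' Generate a Gaussian-peak chromatogram
#'
#' @param cc a [chromatogram_config()].
#' @param conc analyte concentration, ng/mL; peak height is
#'   `height_per_unit_conc * conc`.
#' @param seed integer seed.
#' @return a `chromatogram`: list with regular `time` grid, `intensity`,
#'   and default peak/noise windows (peak +/- 4 sigma; the leading
#'   baseline up to 8 sigma before the apex).
#' @export
generate_chromatogram <- function(cc, conc, seed = 1L) {
  stopifnot(inherits(cc, "chromatogram_config"))
  set.seed(derive_seed(seed, "chromatogram"))
  time <- seq(0, cc$duration, by = 1 / cc$sampling_rate)
  peak <- cc$height_per_unit_conc * conc *
    exp(-(time - cc$peak_center)^2 / (2 * cc$peak_sigma^2))
  intensity <- peak + stats::rnorm(length(time), 0, cc$baseline_noise_sd)
  chromatogram(time, intensity,
               peak_window = cc$peak_center + c(-4, 4) * cc$peak_sigma,
               noise_window = c(0, cc$peak_center - 8 * cc$peak_sigma))
}

#' Combine measurement record frames with differing condition columns
#'
#' @param ... measurement record data.frames (e.g. calibration, spike-set
#'   and stability records); missing columns are filled with NA.
#' @return a single data.frame.
#' @export
bind_records <- function(...) {
  frames <- list(...)
  cols <- unique(unlist(lapply(frames, names)))
  do.call(rbind, lapply(frames, function(f) {
    for (col in setdiff(cols, names(f))) f[[col]] <- NA
    f[cols]
  }))
}

#' Write measurement records to the shared CSV schema
#'
#' @param records data.frame of measurement records (any mix of roles);
#'   missing condition columns are filled with NA.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  cols <- c("analyte_id", "role", "day", "curve", "replicate", "level_ng_ml",
            "temp_c", "time_d", "run_id", "added_ng_ml",
            "area_analyte", "area_is")
  for (col in setdiff(cols, names(records))) records[[col]] <- NA
  utils::write.csv(records[cols], path, row.names = FALSE)
  invisible(path)
}

#' Read measurement records written by [write_measurements()]
#' @param path CSV path.
#' @return data.frame of measurement records.
#' @export
read_measurements <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
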
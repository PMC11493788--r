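test_that("calibration generator reproduces the 54-analysis design deterministically", {
  cfg <- synthetic_config(seed = 11)
  cal <- generate_calibration(cfg)
  expect_equal(nrow(cal), 54)  # 6 levels x 3 curves x 3 days
  expect_equal(sort(unique(cal$level_ng_ml)), c(2, 5, 10, 20, 50, 100))
  expect_true(all(table(cal$level_ng_ml) == 9))

  expect_identical(cal, generate_calibration(synthetic_config(seed = 11)))
  expect_false(identical(cal, generate_calibration(synthetic_config(seed = 12))))
  expect_true(all(cal$area_analyte > 0))
})

test_that("noise-free generator lies exactly on the truth curve", {
  cfg <- noise_free_config(slope = 0.9, intercept = 0.02, quad = -0.01)
  cal <- generate_calibration(cfg)
  x <- cal$level_ng_ml / cfg$is_concentration
  expect_equal(cal$area_analyte / cal$area_is,
               -0.01 * x^2 + 0.9 * x + 0.02, tolerance = 1e-12)
})

test_that("generated variance follows the configured power law", {
  for (k in c(1, 2)) {
    cfg <- synthetic_config(variance_power = k, base_cv = 0.1,
                            day_effect_sd = 0, curves_per_day = 350,
                            days = 1, seed = 20 + k)
    cal <- generate_calibration(cfg)
    y <- cal$area_analyte / cal$area_is
    x <- cal$level_ng_ml / cfg$is_concentration
    s2 <- tapply(y, x, var)
    slope <- coef(lm(log(s2) ~ log(sort(unique(x)))))[2]
    expect_equal(unname(slope), k, tolerance = 0.25)
  }
})

test_that("matrix-effect sets encode the configured multipliers", {
  cfg <- noise_free_config(me_multiplier = 1.28, er_multiplier = 0.93)
  sets <- generate_me_er_sets(cfg)
  expect_equal(sort(unique(sets$level_ng_ml)), c(2, 15, 75))
  s <- split(sets, sets$role)
  expect_equal(nrow(s$me_set1), 9)
  r <- function(d) d$area_analyte / d$area_is
  expect_equal(r(s$me_set1), 1.28 * r(s$me_set2), tolerance = 1e-12)
  expect_equal(r(s$me_set3), 0.93 * r(s$me_set1), tolerance = 1e-12)

  neutral <- generate_me_er_sets(noise_free_config(me_multiplier = 1,
                                                   er_multiplier = 1))
  ns <- split(neutral, neutral$role)
  expect_equal(r(ns$me_set1), r(ns$me_set2))
  expect_equal(r(ns$me_set3), r(ns$me_set1))
})

test_that("simulated ME estimate is unbiased at the configured enhancement", {
  # Monte-Carlo: 1000 replicates/level, +93% enhancement, 10% noise
  cfg <- synthetic_config(me_multiplier = 1.93, base_cv = 0.10, seed = 31)
  sets <- generate_me_er_sets(cfg, replicates = 1000)
  me <- matrix_effect(sets[sets$role == "me_set1", ],
                      sets[sets$role == "me_set2", ])
  expect_equal(me$mean_pct, 193, tolerance = 2 / 193)
})

test_that("stability generator covers the storage grid and decays as configured", {
  cfg <- noise_free_config()
  st <- generate_stability(cfg)
  expect_equal(nrow(st), 54)  # 3 temps x 3 times x 2 concs x 3 reps
  expect_equal(length(unique(st$temp_c)), 3)
  # stable scenario: identical ratios across conditions at a concentration
  r <- st$area_analyte / st$area_is
  expect_true(all(tapply(r, st$level_ng_ml, function(v) diff(range(v))) <
                    1e-12))

  dec <- generate_stability(synthetic_config(base_cv = 0.02, seed = 5),
                            reps = 25, degradation_rate = c("25" = 0.02))
  r <- dec$area_analyte / dec$area_is
  hot28 <- mean(r[dec$temp_c == 25 & dec$time_d == 28 & dec$level_ng_ml == 75])
  hot1 <- mean(r[dec$temp_c == 25 & dec$time_d == 1 & dec$level_ng_ml == 75])
  expect_equal(hot28 / hot1, exp(-0.02 * 27), tolerance = 0.05)
  cold <- r[dec$temp_c == -20 & dec$level_ng_ml == 75]
  expect_equal(mean(cold[dec$time_d[dec$temp_c == -20 &
                                      dec$level_ng_ml == 75] == 28]) /
                 mean(cold[dec$time_d[dec$temp_c == -20 &
                                        dec$level_ng_ml == 75] == 1]),
               1, tolerance = 0.05)
})

test_that("DoE response generator follows the coded effect model", {
  design <- full_factorial(seed = 2)
  resp <- generate_doe_responses(design, analytes = paste0("A", 1:25),
                                 noise_sd = 0.05, seed = 3)
  expect_equal(dim(resp), c(9, 25))

  flat <- generate_doe_responses(design, beta_volume = 0, beta_time = 0,
                                 noise_sd = 0, seed = 3)
  expect_true(all(flat == flat[1, 1]))

  inc <- generate_doe_responses(design, analytes = "A1", beta_volume = 0,
                                beta_time = 0.5, noise_sd = 0, seed = 3)
  ord <- order(design$runs$coded_time)
  expect_true(all(diff(inc[ord, 1][!duplicated(design$runs$coded_time[ord])]) > 0))
})

test_that("chromatogram generator hits the constructed peak height and S/N", {
  cc <- chromatogram_config(height_per_unit_conc = 1000,
                            baseline_noise_sd = 0)
  clean <- generate_chromatogram(cc, conc = 10, seed = 1)
  expect_equal(max(clean$intensity), 10000, tolerance = 1e-6)

  cc_blank <- chromatogram_config(baseline_noise_sd = 20)
  blank <- generate_chromatogram(cc_blank, conc = 0, seed = 2)
  in_peak <- blank$time >= blank$peak_window[1] &
    blank$time <= blank$peak_window[2]
  expect_lt(max(blank$intensity[in_peak]), 20 * 5)

  # constructed height/noise = 30 -> measured S/N = 30 +/- 15%
  cc_sn <- chromatogram_config(height_per_unit_conc = 600,
                               baseline_noise_sd = 20)
  sn <- sapply(1:50, function(s) measure_sn(generate_chromatogram(cc_sn, 1, s)))
  expect_equal(mean(sn), 30, tolerance = 0.15)

  expect_error(chromatogram_config(peak_center = 0.1, peak_sigma = 0.05),
               "4 sigma")
})

test_that("measurement CSV round-trips through the shared schema", {
  cfg <- synthetic_config(seed = 9)
  rec <- bind_records(generate_calibration(cfg),
                      generate_stability(cfg))
  f <- tempfile(fileext = ".csv")
  write_measurements(rec, f)
  back <- read_measurements(f)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$area_analyte, rec$area_analyte, tolerance = 1e-12)
  expect_true(all(is.na(back$temp_c[back$role == "calibrator"])))
})
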
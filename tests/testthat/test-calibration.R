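test_that("variance assessment classifies the generating variance law", {
  # quadratic variance growth -> heteroscedastic, 1/x^2
  cfg <- synthetic_config(variance_power = 2, base_cv = 0.1,
                          day_effect_sd = 0, curves_per_day = 100, days = 1,
                          seed = 41)
  va <- assess_variance(generate_calibration(cfg))
  expect_true(va$heteroscedastic)
  expect_equal(va$chosen_weighting, "1/x^2")
  expect_equal(va$variance_power_estimate, 2, tolerance = 0.3)

  # linear variance growth -> 1/x
  cfg1 <- synthetic_config(variance_power = 1, base_cv = 0.1,
                           day_effect_sd = 0, curves_per_day = 100, days = 1,
                           seed = 42)
  va1 <- assess_variance(generate_calibration(cfg1))
  expect_equal(va1$chosen_weighting, "1/x")

  # constant variance -> homoscedastic, none
  cfg0 <- synthetic_config(variance_power = 0, base_cv = 0.05,
                           day_effect_sd = 0, curves_per_day = 100, days = 1,
                           seed = 43)
  va0 <- assess_variance(generate_calibration(cfg0))
  expect_false(va0$heteroscedastic)
  expect_equal(va0$chosen_weighting, "none")

  # degenerate: zero variance everywhere
  expect_warning(vaz <- assess_variance(records_on_curve(0.05, 1)),
                 "homoscedastic")
  expect_equal(vaz$chosen_weighting, "none")
})

test_that("weighting selection recovers the generating k at realistic noise", {
  # pooled over k in {0,1,2} and base CV in 5-15%
  cases <- expand.grid(k = 0:2, cv = c(0.05, 0.1, 0.15), rep = 1:23)
  want <- c("none", "1/x", "1/x^2")
  hits <- vapply(seq_len(nrow(cases)), function(i) {
    cfg <- synthetic_config(variance_power = cases$k[i],
                            base_cv = cases$cv[i], day_effect_sd = 0,
                            seed = 5000 + i)
    va <- assess_variance(generate_calibration(cfg))
    va$chosen_weighting == want[cases$k[i] + 1]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("weighted fit recovers exact coefficients and matches the normal-equations oracle", {
  # noise-free data on the printed first-analyte line
  rec <- records_on_curve(0.0579, 0.8092)
  for (wt in c("none", "1/x", "1/x^2")) {
    m <- fit_calibration(rec, wt, "linear")
    expect_equal(unname(m$coefficients[c("a0", "a1")]), c(0.0579, 0.8092),
                 tolerance = 1e-12)
  }

  # oracle: solve the weighted normal equations directly
  set.seed(77)
  for (i in 1:20) {
    n <- sample(6:15, 1)
    x <- runif(n, 0.1, 5)
    y <- 0.5 + 0.9 * x + rnorm(n, 0, 0.1)
    rec <- data.frame(analyte_id = "Z", role = "calibrator", day = 1,
                      curve = 1, replicate = seq_len(n),
                      level_ng_ml = x * 20, area_analyte = y * 1e5,
                      area_is = 1e5)
    wt <- sample(c("none", "1/x", "1/x^2"), 1)
    order <- sample(c("linear", "quadratic"), 1)
    m <- fit_calibration(rec, wt, order)
    w <- switch(wt, none = rep(1, n), "1/x" = 1 / x, "1/x^2" = 1 / x^2)
    X <- if (order == "linear") cbind(1, x) else cbind(1, x, x^2)
    beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
    got <- m$coefficients[c("a0", "a1", if (order == "quadratic") "a2")]
    expect_equal(unname(got), unname(drop(beta)), tolerance = 1e-8)
  }

  # weight-mass invariance: duplicating every point leaves coefficients alone
  rec <- records_on_curve(0.1, 1.2, days = 1, curves = 1)
  rec$area_analyte <- rec$area_analyte * (1 + c(0.01, -0.01, 0.02, 0, -0.02, 0.01))
  m1 <- fit_calibration(rec, "1/x", "linear")
  m2 <- fit_calibration(rbind(rec, rec), "1/x", "linear")
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-12)
})

test_that("weighted residuals satisfy the normal-equation identities", {
  cfg <- synthetic_config(seed = 55)
  cal <- generate_calibration(cfg)
  x <- cal$level_ng_ml / 20
  y <- cal$area_analyte / cal$area_is
  for (wt in c("none", "1/x^2")) {
    m <- fit_calibration(cal, wt, "quadratic")
    w <- switch(wt, none = rep(1, length(x)), "1/x^2" = 1 / x^2)
    r <- y - predict(m, x)
    for (col in list(rep(1, length(x)), x, x^2)) {
      expect_equal(sum(w * r * col), 0, tolerance = 1e-8)
    }
  }
})

test_that("model order selection separates straight from saturating curves", {
  # noise-free linear -> linear with negligible Mandel F
  lin <- records_on_curve(0.0579, 0.8092)
  lin$area_analyte <- lin$area_analyte * (1 + rep_len(c(1e-9, -1e-9), nrow(lin)))
  sel <- select_model_order(lin, "1/x^2")
  expect_equal(sel$order, "linear")

  # noise-free saturating quadratic (printed sulfonate coefficients)
  quad <- records_on_curve(0.0339, 5.5136, -0.0538)
  quad$area_analyte <- quad$area_analyte * (1 + rep_len(c(1e-7, -1e-7), nrow(quad)))
  expect_equal(select_model_order(quad, "1/x^2")$order, "quadratic")
})

test_that("order selection recovers a mixed 20 linear / 5 quadratic panel", {
  truth <- rep(c("linear", "quadratic"), c(20, 5))
  got <- vapply(seq_along(truth), function(i) {
    cfg <- synthetic_config(quad = if (truth[i] == "quadratic") -0.04 else 0,
                            base_cv = 0.05, seed = 600 + i)
    select_model_order(generate_calibration(cfg), "1/x^2")$order
  }, character(1))
  expect_gte(sum(got == truth), 23)
})

test_that("adding the quadratic term never increases weighted RSS", {
  for (s in 1:10) {
    cal <- generate_calibration(synthetic_config(seed = 700 + s))
    x <- cal$level_ng_ml / 20
    y <- cal$area_analyte / cal$area_is
    w <- 1 / x^2
    rss <- function(order) {
      m <- fit_calibration(cal, "1/x^2", order)
      sum(w * (y - predict(m, x))^2)
    }
    expect_lte(rss("quadratic"), rss("linear") + 1e-12)
  }
})

test_that("back-calculation inverts the printed equations", {
  pub <- published_models()
  pfba <- pub[pub$analyte_id == "PFBA", ]
  m <- calibration_model(pfba$a0, pfba$a1)
  expect_equal(back_calculate(m, 0.4625), 10, tolerance = 1e-9)
  expect_equal(back_calculate(m, pfba$a0), 0)

  # quadratic: the ascending-branch root, not the mirror root
  hxs <- pub[pub$analyte_id == "L-PFHxS", ]
  mq <- calibration_model(hxs$a0, hxs$a1, hxs$a2)
  y_at_2.5 <- hxs$a2 * 2.5^2 + hxs$a1 * 2.5 + hxs$a0
  expect_equal(back_calculate(mq, y_at_2.5), 50, tolerance = 1e-9)
  # mirror root is ~ 100x further out and must not be returned
  mirror <- (-hxs$a1 - sqrt(hxs$a1^2 - 4 * hxs$a2 * (hxs$a0 - y_at_2.5))) /
    (2 * hxs$a2)
  expect_gt(mirror * 20, 1900)

  # out-of-range responses flagged non-quantifiable
  expect_true(is.na(back_calculate(m, pfba$a0 + pfba$a1 * 100)))
  expect_error(back_calculate(calibration_model(0.1, -2), 0.5),
               "non-positive slope")
})

test_that("predict/back_calculate round-trip to 1e-9 relative", {
  models <- list(calibration_model(0.0579, 0.8092),
                 calibration_model(0.0339, 5.5136, -0.0538),
                 calibration_model(0.0235, 0.7061, 0.0144))
  x <- c(0.1, 0.25, 0.5, 1, 2.5, 5)
  for (m in models) {
    back <- back_calculate(m, predict(m, x))
    expect_equal(back, x * 20, tolerance = 1e-9)
  }
})
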
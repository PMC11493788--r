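test_that("full factorial enumerates and codes the design space", {
  d <- full_factorial(seed = 4)
  expect_equal(nrow(d$runs), 9)
  expect_setequal(unique(d$runs$volume), c(250, 500, 750))
  expect_setequal(unique(d$runs$time), c(10, 20, 30))
  expect_equal(nrow(unique(d$runs[c("volume", "time")])), 9)
  expect_setequal(unique(d$runs$coded_volume), c(-1, 0, 1))

  # balance: each level of each factor appears equally often
  expect_true(all(table(d$runs$volume) == 3))
  expect_true(all(table(d$runs$time) == 3))

  expect_equal(nrow(full_factorial(list(a = 1:2), seed = 1)$runs), 2)
  expect_equal(nrow(full_factorial(list(a = 1:2, b = 1:2, c = 1:2),
                                   seed = 1)$runs), 8)
  expect_error(full_factorial(list(a = 1), seed = 1), ">= 2 levels")
  expect_error(full_factorial(list(), seed = 1), ">= 1 factor")

  # run order is shuffled but reproducible under the seed
  expect_identical(full_factorial(seed = 4)$runs, d$runs)
})

test_that("PCA matches an eigendecomposition oracle and reconstructs", {
  set.seed(12)
  for (i in 1:5) {
    m <- matrix(rnorm(9 * 25), 9, 25,
                dimnames = list(NULL, paste0("A", 1:25)))
    pc <- pca_decompose(m, "center")
    centred <- scale(m, center = TRUE, scale = FALSE)
    eig <- eigen(crossprod(centred) / (nrow(m) - 1), symmetric = TRUE)
    k <- min(dim(centred)) - 1
    expect_equal(pc$explained_variance[1:k],
                 (eig$values / sum(eig$values))[1:k], tolerance = 1e-8)
    # loadings equal up to sign; scores are the projected data
    for (j in 1:3) {
      expect_equal(unname(abs(pc$loadings[, j])), abs(eig$vectors[, j]),
                   tolerance = 1e-8)
    }
    expect_equal(unname(pc$scores), unname(centred %*% pc$loadings),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # orthonormal loadings, full reconstruction
    expect_equal(crossprod(pc$loadings), diag(ncol(pc$loadings)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(unname(pc$scores %*% t(pc$loadings)), unname(centred),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(sum(pc$explained_variance), 1, tolerance = 1e-12)
    expect_true(all(diff(pc$explained_variance) <= 1e-12))
  }

  rank1 <- outer(1:9, seq(0.5, 2, length.out = 4))
  colnames(rank1) <- paste0("A", 1:4)
  expect_equal(pca_decompose(rank1, "center")$explained_variance[1], 1,
               tolerance = 1e-12)

  const <- cbind(A1 = rep(1, 9), A2 = rnorm(9))
  expect_error(pca_decompose(const, "autoscale"), "A1")
})

test_that("MLR recovers coded-factor effects and respects orthogonality", {
  d <- full_factorial(seed = 6)
  fit <- suppressWarnings(mlr_fit(d$runs$coded_volume, d))
  est <- setNames(fit$estimate, fit$term)
  expect_equal(unname(est[c("(Intercept)", "volume", "time")]), c(0, 1, 0),
               tolerance = 1e-12)

  resp <- generate_doe_responses(d, analytes = "A1", intercept = 1,
                                 beta_volume = 0.05, beta_time = 0.5,
                                 noise_sd = 0, seed = 1)
  fit2 <- suppressWarnings(mlr_fit(resp[, 1], d))
  est2 <- setNames(fit2$estimate, fit2$term)
  expect_equal(unname(est2["volume"]), 0.05, tolerance = 1e-9)
  expect_equal(unname(est2["time"]), 0.5, tolerance = 1e-9)

  # balanced design: dropping the interaction leaves main effects unchanged
  set.seed(3)
  noisy <- resp[, 1] + rnorm(9, 0, 0.05)
  with_int <- mlr_fit(noisy, d, include_interaction = TRUE)
  without <- mlr_fit(noisy, d, include_interaction = FALSE)
  get <- function(f, term) f$estimate[f$term == term]
  expect_equal(get(with_int, "volume"), get(without, "volume"),
               tolerance = 1e-9)
  expect_equal(get(with_int, "time"), get(without, "time"), tolerance = 1e-9)

  expect_error(mlr_fit(1:5, d), "mismatch")
})

test_that("the full DoE analysis flags a modest time effect over a minimal volume effect", {
  d <- full_factorial(seed = 8)
  sig_time <- vapply(1:20, function(s) {
    resp <- generate_doe_responses(d, analytes = paste0("A", 1:25),
                                   intercept = 1, beta_volume = 0.01,
                                   beta_time = 0.2, noise_sd = 0.05,
                                   seed = 100 + s)
    res <- doe_analysis(resp, d, include_interaction = FALSE)
    p <- setNames(res$mlr$p_value, res$mlr$term)
    est <- setNames(res$mlr$estimate, res$mlr$term)
    c(time_sig = unname(p["time"]) < 0.05,
      vol_small = unname(abs(est["volume"]) < abs(est["time"])))
  }, logical(2))
  expect_gte(mean(sig_time["time_sig", ]), 0.8)
  expect_gte(mean(sig_time["vol_small", ]), 0.9)
})
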
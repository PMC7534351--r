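test_that("generation is deterministic under the seed and varies across seeds", {
  sp <- synthetic_spec(n = 22, p = 6, seed = 7)
  expect_identical(make_descriptor_pool(sp), make_descriptor_pool(sp))
  expect_identical(simulate_qsar_dataset(sp)$y, simulate_qsar_dataset(sp)$y)
  sp2 <- synthetic_spec(n = 22, p = 6, seed = 8)
  expect_false(identical(make_descriptor_pool(sp), make_descriptor_pool(sp2)))
})

test_that("empirical pairwise correlation tracks the requested value", {
  sp0 <- synthetic_spec(n = 200, p = 6, correlation = 0, seed = 1)
  r0 <- cor(make_descriptor_pool(sp0))
  expect_lt(mean(abs(r0[upper.tri(r0)])), 0.25)

  sp8 <- synthetic_spec(n = 500, p = 6, correlation = 0.8, seed = 2)
  r8 <- cor(make_descriptor_pool(sp8))
  expect_true(all(abs(r8[upper.tri(r8)] - 0.8) < 0.08))

  expect_error(synthetic_spec(correlation = 1), "\\[0, 1\\)")
})

test_that("descriptor-scaled pools mimic real descriptor magnitudes", {
  sp <- synthetic_spec(n = 500, p = 6, scales = "descriptor", noise_sd = 0.1, seed = 3)
  X <- make_descriptor_pool(sp)
  mu <- colMeans(X)
  # columns recycle the archetype scales: tiny INTEGY-like first, PSA-like fourth
  expect_lt(abs(mu[1] - 0.03), 0.01)
  expect_lt(abs(mu[4] - 118), 5)
})

test_that("planted responses have the requested linear structure", {
  sp0 <- synthetic_spec(n = 30, p = 5, active_set = c(1, 3), betas = c(2, -3),
                        intercept = 1, noise_sd = 0, seed = 4)
  X <- make_descriptor_pool(sp0)
  y <- plant_response(X, sp0)
  expect_equal(y, 1 + 2 * X[, 1] - 3 * X[, 3], tolerance = 1e-12)
  fit <- fit_mlr(qsar_dataset(X[, c(1, 3)], y))
  expect_equal(unname(coef(fit)), c(1, 2, -3), tolerance = 1e-10)

  sp1 <- synthetic_spec(n = 1000, p = 5, active_set = c(1, 3), betas = c(2, -3),
                        intercept = 1, noise_sd = 0.1, seed = 5)
  X1 <- make_descriptor_pool(sp1)
  y1 <- plant_response(X1, sp1)
  resid_true <- y1 - (1 + 2 * X1[, 1] - 3 * X1[, 3])
  expect_lt(abs(sd(resid_true) - 0.1), 0.01)
})

test_that("a null model fits nothing", {
  sp <- synthetic_spec(n = 1000, p = 4, active_set = integer(), betas = numeric(),
                       intercept = 7, noise_sd = 1, seed = 6)
  X <- make_descriptor_pool(sp)
  y <- plant_response(X, sp)
  r2 <- vapply(1:4, function(j) {
    fit_mlr(qsar_dataset(X[, j, drop = FALSE], y), loo = FALSE)$stats$r.squared
  }, numeric(1))
  expect_true(all(r2 < 0.05))
})

test_that("coefficients converge to the planted truth as noise shrinks", {
  for (noise in c(0, 0.01, 0.1)) {
    sp <- synthetic_spec(n = 200, p = 6, active_set = c(2, 4), betas = c(1.5, -1),
                         intercept = 7, noise_sd = noise, seed = 10)
    ds <- simulate_qsar_dataset(sp)
    est <- coef(fit_mlr(ds, descriptors = c("D2", "D4"), loo = FALSE))
    tol <- if (noise == 0) 1e-10 else 4 * noise / sqrt(200) * 3
    expect_equal(unname(est), c(7, 1.5, -1), tolerance = max(tol, 1e-10))
  }
})

test_that("noise calibration hits the target population R2", {
  sp <- synthetic_spec(n = 5000, p = 8, correlation = 0.3, active_set = 1:4,
                       betas = c(0.6, -0.5, 0.45, -0.4), target_r2 = 0.9, seed = 12)
  ds <- simulate_qsar_dataset(sp)
  fit <- fit_mlr(ds, descriptors = paste0("D", 1:4), loo = FALSE)
  expect_equal(fit$stats$r.squared, 0.9, tolerance = 0.02)
})

test_that("recovery suites share one truth across distinct datasets", {
  suite <- make_recovery_suite(20, synthetic_spec(seed = 1))
  expect_identical(nrow(suite), 20L)
  truth <- attr(suite, "truth")
  expect_identical(truth$active, c("D1", "D2", "D3", "D4"))
  ys <- vapply(suite$dataset, function(d) d$y[1], numeric(1))
  expect_identical(length(unique(ys)), 20L)
})
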
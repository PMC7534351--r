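test_that("fit_mlr solves the toy closed-form problem", {
  # normal equations by hand for {(0,1),(1,3),(2,5)}: slope 2, intercept 1
  ds <- qsar_dataset(matrix(c(0, 1, 2), ncol = 1, dimnames = list(NULL, "x")),
                     c(1, 3, 5))
  fit <- fit_mlr(ds)
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-12)
  expect_equal(fit$stats$r.squared, 1, tolerance = 1e-12)
})

test_that("noiseless planted models are recovered to machine precision", {
  withr::with_seed(3, {
    X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("x1", "x2")))
    y <- 1 + 2 * X[, 1] - 3 * X[, 2]
  })
  fit <- fit_mlr(qsar_dataset(X, y))
  expect_equal(unname(coef(fit)), c(1, 2, -3), tolerance = 1e-12)
  expect_equal(fit$stats$rss, 0, tolerance = 1e-18)
  expect_equal(fit$stats$sigma, 0, tolerance = 1e-9)
  expect_equal(fit$loo$q.squared, 1, tolerance = 1e-9)
})

test_that("fit agrees with the normal-equations and lm oracles", {
  for (seed in 1:5) {
    prob <- random_problem(n = 25, p = 4, seed = seed)
    fit <- fit_mlr(qsar_dataset(prob$X, prob$y))
    # brute-force normal equations
    Xd <- cbind(1, prob$X)
    beta_ne <- solve(crossprod(Xd), crossprod(Xd, prob$y))
    expect_equal(unname(coef(fit)), as.numeric(beta_ne), tolerance = 1e-8)
    # independent lm route
    orc <- oracle_fit(prob$X, prob$y)
    expect_equal(unname(coef(fit)), unname(orc$coefficients), tolerance = 1e-10)
    expect_equal(fit$stats$r.squared, orc$r.squared, tolerance = 1e-12)
    expect_equal(fit$stats$sigma, orc$sigma, tolerance = 1e-12)
    expect_equal(fit$stats$fstatistic, orc$fstatistic, tolerance = 1e-10)
  }
})

test_that("F from (R2, n, p) equals MSR/MSE", {
  prob <- random_problem(n = 18, p = 3, seed = 9)
  fit <- fit_mlr(qsar_dataset(prob$X, prob$y))
  msr <- (fit$stats$tss - fit$stats$rss) / fit$p
  mse <- fit$stats$rss / (fit$n - fit$p - 1)
  expect_equal(fit$stats$fstatistic, msr / mse, tolerance = 1e-10)
})

test_that("adding a descriptor never decreases R2 (nested monotonicity)", {
  for (seed in 1:4) {
    prob <- random_problem(n = 20, p = 5, seed = 100 + seed)
    ds <- qsar_dataset(prob$X, prob$y)
    r2 <- vapply(1:5, function(k) {
      fit_mlr(ds, descriptors = paste0("D", 1:k), loo = FALSE)$stats$r.squared
    }, numeric(1))
    expect_true(all(diff(r2) >= -1e-12))
  }
})

test_that("row permutation changes no statistic", {
  prob <- random_problem(n = 15, p = 3, seed = 21)
  ds <- qsar_dataset(prob$X, prob$y)
  perm <- withr::with_seed(1, sample(15))
  dsp <- qsar_dataset(prob$X[perm, ], prob$y[perm])
  f1 <- fit_mlr(ds); f2 <- fit_mlr(dsp)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
  expect_equal(f1$stats, f2$stats, tolerance = 1e-12)
  expect_equal(f1$loo$press, f2$loo$press, tolerance = 1e-12)
})

test_that("collinear descriptors raise an error naming the columns", {
  withr::with_seed(5, {
    X <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  })
  X <- cbind(X, twin = X[, "a"])
  y <- rnorm(15)
  expect_error(fit_mlr(qsar_dataset(X, y)), "twin")
})

test_that("leave-one-out shortcut matches refit loop and the lm oracle", {
  ds_raf <- build_qsar_dataset(raf_descriptor_table(), "pIC50_RAF1",
                               descriptors = c("IW1", "FLEX"))
  hat <- loo_cv(ds_raf, method = "hat")
  refit <- loo_cv(ds_raf, method = "refit")
  orc <- oracle_loo(ds_raf$X, ds_raf$y)
  expect_equal(hat$press, refit$press, tolerance = 1e-12)
  expect_equal(hat$heldout$predicted, refit$heldout$predicted, tolerance = 1e-12)
  expect_equal(hat$press, orc$press, tolerance = 1e-10)
  expect_equal(hat$q.squared, orc$q.squared, tolerance = 1e-10)

  for (seed in 1:8) {
    prob <- random_problem(n = 14, p = 3, seed = 200 + seed)
    ds <- qsar_dataset(prob$X, prob$y)
    expect_equal(loo_cv(ds)$press, loo_cv(ds, method = "refit")$press,
                 tolerance = 1e-10)
  }
})

test_that("Q2 <= R2 and PRESS >= RSS on every dataset tested", {
  for (seed in 1:10) {
    prob <- random_problem(n = 12 + seed, p = 1 + seed %% 4, seed = 300 + seed,
                           noise_sd = 0.5)
    fit <- fit_mlr(qsar_dataset(prob$X, prob$y))
    expect_lte(fit$loo$q.squared, fit$stats$r.squared + 1e-12)
    expect_gte(fit$loo$press, fit$stats$rss - 1e-12)
  }
})

test_that("degrees-of-freedom preconditions are enforced", {
  withr::with_seed(2, {
    X <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b")))
  })
  expect_error(fit_mlr(qsar_dataset(X, rnorm(4))), NA) # n = p + 2 fits
  ds <- qsar_dataset(X, rnorm(4))
  expect_error(loo_cv(ds), "n >= p \\+ 3")
  expect_error(qsar_dataset(X[1:3, ], rnorm(3)), "insufficient degrees of freedom")
})

test_that("prediction is the linear form and validates inputs", {
  tbl <- raf_descriptor_table()
  fit <- fit_mlr(tbl, "pIC50_RAF1", c("IW1", "FLEX"))
  # arithmetic on the published coefficients for compound 1zb:
  # 13.505 - 35.647*0.027 - 1.367*3.237 = 8.117... (3 dp: 8.118)
  published <- c(`(Intercept)` = 13.505, IW1 = -35.647, FLEX = -1.367)
  row_1zb <- data.frame(IW1 = 0.027, FLEX = 3.237)
  expect_equal(
    round(published[1] + published[2] * 0.027 + published[3] * 3.237, 3),
    8.118, ignore_attr = TRUE
  )
  # the refitted model predicts close to the published form
  expect_equal(predict(fit, row_1zb), 8.118, tolerance = 0.05)
  # intercept exactly for an all-zero row
  expect_equal(predict(fit, data.frame(IW1 = 0, FLEX = 0)),
               unname(coef(fit)[1]), tolerance = 1e-12)
  expect_equal(predict(fit), fit$fitted, tolerance = 1e-12)
  expect_error(predict(fit, data.frame(IW1 = 0.03)), "FLEX")
})

test_that("tidy/glance/augment expose the fit as tibbles", {
  fit <- fit_mlr(raf_descriptor_table(), "pIC50_RAF1", c("IW1", "FLEX"))
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "IW1", "FLEX"))
  expect_equal(td$estimate, unname(coef(fit)))
  gl <- glance(fit)
  expect_identical(gl$n, 9L)
  expect_equal(gl$q.squared, fit$loo$q.squared)
  au <- augment(fit)
  expect_identical(nrow(au), 9L)
  expect_equal(au$.resid, fit$residuals)
  expect_equal(au$observed - au$.loo_resid, au$.loo_pred)
})

test_that("model JSON round-trips the equation and fingerprint", {
  fit <- fit_mlr(raf_descriptor_table(), "pIC50_RAF1", c("IW1", "FLEX"))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(x$intercept, unname(coef(fit)[1]))
  expect_equal(x$coefficients$IW1, unname(coef(fit)["IW1"]))
  expect_equal(x$loo$q.squared, fit$loo$q.squared)
  expect_match(x$training_data_md5, "^[0-9a-f]{32}$")
})
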
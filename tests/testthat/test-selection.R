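raf_pool <- function() build_qsar_dataset(raf_descriptor_table(), "pIC50_RAF1")

test_that("evaluate_subset fitness equals the corresponding diagnostic exactly", {
  ds <- raf_pool()
  res_q2 <- evaluate_subset(ds, c("IW1", "FLEX"), metric = "q2")
  expect_identical(res_q2$fitness, res_q2$model$loo$q.squared)
  expect_equal(res_q2$fitness, loo_cv(ds, descriptors = c("IW1", "FLEX"))$q.squared)
  res_r2 <- evaluate_subset(ds, c("IW1", "FLEX"), metric = "r2")
  expect_identical(res_r2$fitness, res_r2$model$stats$r.squared)
  expect_error(evaluate_subset(ds, "nope"), "Unknown")
  expect_error(evaluate_subset(ds, character()), "at least one")
})

test_that("infeasible subsets return a -Inf sentinel inside searches", {
  withr::with_seed(31, {
    X <- matrix(rnorm(24), 12, 2, dimnames = list(NULL, c("a", "b")))
  })
  X <- cbind(X, twin = X[, "a"])
  ds <- qsar_dataset(X, rnorm(12))
  res <- evaluate_subset(ds, c("a", "twin"), sentinel = TRUE)
  expect_identical(res$fitness, -Inf)
  expect_null(res$model)
  expect_error(evaluate_subset(ds, c("a", "twin")), "rank deficient")
})

test_that("exhaustive search enumerates and ranks all subsets", {
  ds <- raf_pool()
  ranked <- exhaustive_search(ds, max_size = 2, metric = "q2")
  expect_identical(nrow(ranked), 21L) # 6 singletons + 15 pairs
  # independent brute-force enumeration via the lm-based oracle
  pool <- ds$descriptor_names
  subsets <- c(as.list(pool), combn(pool, 2, simplify = FALSE))
  oracle <- vapply(subsets, function(s) {
    oracle_loo(ds$X[, s, drop = FALSE], ds$y)$q.squared
  }, numeric(1))
  keys <- vapply(subsets, paste, character(1), collapse = "+")
  expect_equal(ranked$fitness, unname(oracle[match(ranked$subset, keys)]),
               tolerance = 1e-10)
  expect_true(all(ranked$fitness[1] >= ranked$fitness))
  # deterministic tie-break ordering: fitness desc, size asc, lexicographic
  reord <- order(-ranked$fitness, ranked$size, ranked$subset)
  expect_identical(reord, seq_len(nrow(ranked)))
})

test_that("single-descriptor pool yields that single subset", {
  withr::with_seed(17, {
    X <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "only"))
    y <- 1 + X[, 1] + rnorm(10, sd = 0.1)
  })
  ranked <- exhaustive_search(qsar_dataset(X, y), max_size = 1)
  expect_identical(nrow(ranked), 1L)
  expect_identical(ranked$descriptors[[1]], "only")
})

test_that("exhaustive search recovers a planted active pair", {
  sp <- synthetic_spec(n = 22, p = 8, correlation = 0.3, active_set = c(2, 5),
                       betas = c(0.8, -0.7), noise_sd = 0.05, seed = 11)
  ds <- simulate_qsar_dataset(sp)
  ranked <- exhaustive_search(ds, max_size = 2)
  expect_setequal(ranked$descriptors[[1]], c("D2", "D5"))
})

test_that("subset-count guard triggers with advice to use the GA", {
  ds <- raf_pool()
  expect_error(exhaustive_search(ds, max_size = 4, guard = 10), "ga_search")
  expect_error(exhaustive_search(ds, max_size = 10), "exceeds the pool")
})

test_that("GA is reproducible and respects its constraints", {
  sp <- synthetic_spec(n = 20, p = 10, correlation = 0.2, active_set = c(1, 6),
                       betas = c(0.7, -0.6), seed = 5)
  ds <- simulate_qsar_dataset(sp)
  cfg <- selection_config(max_subset_size = 3, population = 40,
                          generations = 20, seed = 42)
  g1 <- ga_search(ds, cfg)
  g2 <- ga_search(ds, cfg)
  expect_identical(g1$best$descriptors, g2$best$descriptors)
  expect_identical(g1$history, g2$history)
  expect_lte(length(g1$best$descriptors), 3)
  expect_true(is.finite(g1$best$fitness))
  # a different seed may explore differently but remains feasible
  g3 <- ga_search(ds, selection_config(max_subset_size = 3, population = 40,
                                       generations = 20, seed = 43))
  expect_lte(length(g3$best$descriptors), 3)
})

test_that("GA matches the exhaustive optimum on a small pool", {
  sp <- synthetic_spec(n = 22, p = 9, correlation = 0.3, active_set = c(1, 4, 7),
                       betas = c(0.6, -0.5, 0.45), seed = 23)
  ds <- simulate_qsar_dataset(sp)
  best_ex <- exhaustive_search(ds, max_size = 3)$fitness[1]
  g <- ga_search(ds, selection_config(max_subset_size = 3, population = 60,
                                      generations = 40, seed = 7))
  expect_equal(g$best$fitness, best_ex, tolerance = 1e-12)
})

test_that("GA returns the full set when the pool equals the size cap", {
  withr::with_seed(19, {
    X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- 1 + X[, 1] - X[, 2] + 0.5 * X[, 3] + rnorm(20, sd = 0.05)
  })
  ds <- qsar_dataset(X, y)
  g <- ga_search(ds, selection_config(max_subset_size = 3, population = 20,
                                      generations = 15, seed = 2))
  expect_setequal(g$best$descriptors, c("a", "b", "c"))
  expect_error(
    ga_search(ds, selection_config(max_subset_size = 5, population = 20,
                                   generations = 5)),
    "exceeds the pool"
  )
})

test_that("pairwise-correlation guard excludes collinear subsets", {
  withr::with_seed(29, {
    x1 <- rnorm(20)
    X <- cbind(a = x1, b = x1 + rnorm(20, sd = 0.01), c = rnorm(20))
    y <- 1 + x1 + rnorm(20, sd = 0.1)
  })
  ds <- qsar_dataset(X, y)
  ranked <- exhaustive_search(ds, max_size = 2, max_cor = 0.95)
  ab <- ranked[ranked$subset == "a+b", ]
  expect_identical(ab$fitness, -Inf)
})
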
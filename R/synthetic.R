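#' Specification of a synthetic QSAR benchmark dataset
#'
#' Describes a correlated Gaussian descriptor pool with a planted linear
#' pIC50 response, the structure the regression and selection machinery
#' assumes. Defaults mirror the regime of the bundled kinase study: 22
#' compounds, a pool of 20 descriptors of which 4 carry signal, and
#' residual noise calibrated analytically so that the true model explains
#' about 90% of the response variance (the weaker of the two published
#' fits).
#'
#' @param n Number of compounds (rows).
#' @param p Number of descriptors in the pool.
#' @param correlation Common pairwise correlation of the descriptor pool,
#'   in \[0, 1).
#' @param active_set Integer indices of the truly predictive descriptors.
#' @param betas True coefficients of the active descriptors (pIC50 per
#'   descriptor unit).
#' @param intercept True intercept (pIC50 units).
#' @param noise_sd Residual standard deviation in pIC50 units; `NULL`
#'   (default) calibrates it with [calibrate_noise()] to `target_r2`.
#' @param target_r2 Population R-squared used when `noise_sd` is `NULL`.
#' @param scales `"unit"` (columns with mean 0, sd 1 -- the default, so
#'   coefficients and noise share a scale) or `"descriptor"` (columns
#'   rescaled to ranges mimicking real molecular-descriptor magnitudes,
#'   from INTEGY-moment-sized 0.01-0.05 up to polar-surface-area-sized
#'   99-137).
#' @param seed Integer RNG seed; generation is fully deterministic given
#'   the spec.
#'
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 22, p = 20, correlation = 0.3,
                           active_set = 1:4,
                           betas = c(0.6, -0.5, 0.45, -0.4),
                           intercept = 7.5, noise_sd = NULL,
                           target_r2 = 0.9,
                           scales = c("unit", "descriptor"), seed = 1) {
  scales <- match.arg(scales)
  stopifnot(n >= 3, p >= 1, length(betas) == length(active_set))
  if (correlation < 0 || correlation >= 1) {
    abort("`correlation` must lie in [0, 1).")
  }
  if (length(active_set) && (min(active_set) < 1 || max(active_set) > p)) {
    abort("`active_set` indices must lie in 1..p.")
  }
  spec <- structure(
    list(n = as.integer(n), p = as.integer(p), correlation = correlation,
         active_set = as.integer(active_set), betas = as.numeric(betas),
         intercept = intercept, noise_sd = noise_sd, scales = scales,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
  if (is.null(noise_sd)) {
    spec <- calibrate_noise(spec, target_r2)
  } else if (noise_sd < 0) {
    abort("`noise_sd` must be non-negative.")
  }
  spec
}

# Per-column target (mean, sd); six archetype ranges recycled across the
# pool, chosen to mimic the magnitudes of real descriptor families.
DESCRIPTOR_ARCHETYPES <- list(
  c(0.01, 0.05),   # INTEGY-moment-like
  c(0.02, 0.13),   # second INTEGY moment
  c(2.7, 5.0),     # flexibility-like
  c(99, 137),      # polar-surface-area-like
  c(5.9, 29),      # pharmacophore-triplet-count-like
  c(0, 2.9)        # hydrophobic-volume-difference-like
)

spec_column_scales <- function(spec) {
  if (spec$scales == "unit") {
    list(mu = rep(0, spec$p), sd = rep(1, spec$p))
  } else {
    ranges <- DESCRIPTOR_ARCHETYPES[((seq_len(spec$p) - 1) %% 6) + 1]
    list(
      mu = vapply(ranges, mean, numeric(1)),
      sd = vapply(ranges, function(r) (r[2] - r[1]) / 4, numeric(1))
    )
  }
}

#' Calibrate residual noise to a target population R-squared
#'
#' The signal variance of the planted model is
#' \eqn{\beta' \Sigma \beta} with \eqn{\Sigma} the equicorrelated
#' covariance of the active descriptors on their generated scales; solving
#' \eqn{R^2 = \sigma_s^2 / (\sigma_s^2 + \sigma^2)} for \eqn{\sigma} gives
#' the noise standard deviation analytically, with no simulation.
#'
#' @param spec A [synthetic_spec()].
#' @param target_r2 Desired population R-squared in (0, 1).
#' @return The spec with `noise_sd` set.
#' @export
calibrate_noise <- function(spec, target_r2 = 0.9) {
  stopifnot(inherits(spec, "synthetic_spec"), target_r2 > 0, target_r2 < 1)
  if (!length(spec$active_set)) {
    abort("Cannot calibrate noise for a null model (empty active set).")
  }
  sc <- spec_column_scales(spec)
  sds <- sc$sd[spec$active_set]
  k <- length(sds)
  Sigma <- (diag(1 - spec$correlation, k) + spec$correlation) * outer(sds, sds)
  var_signal <- as.numeric(t(spec$betas) %*% Sigma %*% spec$betas)
  spec$noise_sd <- sqrt(var_signal * (1 - target_r2) / target_r2)
  spec
}

#' Generate a correlated descriptor pool
#'
#' Draws an n x p Gaussian matrix with common pairwise correlation
#' `spec$correlation` (one shared latent factor plus independent noise),
#' then shifts and scales each column to its target location (see the
#' `scales` argument of [synthetic_spec()]). Fully reproducible from
#' `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return An n x p numeric matrix with columns `D1..Dp`.
#' @export
make_descriptor_pool <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sc <- spec_column_scales(spec)
  withr::with_seed(spec$seed, {
    common <- rnorm(spec$n)
    Z <- matrix(rnorm(spec$n * spec$p), spec$n, spec$p)
    latent <- sqrt(spec$correlation) * common + sqrt(1 - spec$correlation) * Z
    X <- sweep(sweep(latent, 2, sc$sd, `*`), 2, sc$mu, `+`)
    colnames(X) <- paste0("D", seq_len(spec$p))
    X
  })
}

#' Plant a linear response on a descriptor matrix
#'
#' \eqn{y = \beta_0 + \sum_j \beta_j x_j + \varepsilon},
#' \eqn{\varepsilon \sim N(0, \sigma^2)}, with the active columns and
#' coefficients taken from the spec. The noise stream is seeded from
#' `spec$seed` (offset from the pool's stream so descriptors and noise are
#' independent), making the pair (pool, response) jointly reproducible.
#'
#' @param X Descriptor matrix with at least `max(spec$active_set)` columns.
#' @param spec A [synthetic_spec()].
#' @return Numeric response vector of length `nrow(X)`.
#' @export
plant_response <- function(X, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (ncol(X) < max(c(spec$active_set, 0))) {
    abort("`X` has fewer columns than the largest active index.")
  }
  signal <- spec$intercept +
    as.numeric(X[, spec$active_set, drop = FALSE] %*% spec$betas)
  withr::with_seed(spec$seed + 500003L, {
    signal + rnorm(nrow(X), sd = spec$noise_sd)
  })
}

#' Generate a simulated qsar_dataset in one call
#'
#' Convenience wrapper: descriptor pool plus planted response, packaged as
#' a `qsar_dataset`.
#'
#' @param spec A [synthetic_spec()].
#' @return A `qsar_dataset`.
#' @export
simulate_qsar_dataset <- function(spec) {
  X <- make_descriptor_pool(spec)
  qsar_dataset(X, plant_response(X, spec), response = "pIC50_sim")
}

#' Generate a suite of replicate datasets with shared truth
#'
#' Produces `count` datasets from the same spec under consecutive seeds
#' (`spec$seed`, `spec$seed + 1`, ...), together with the ground truth
#' (active descriptor names, coefficients, intercept, noise), for
#' parameter-recovery and selection-power studies.
#'
#' @param count Number of replicates (>= 1).
#' @param base_spec A [synthetic_spec()].
#' @return A tibble with columns `seed`, `dataset` (list of
#'   `qsar_dataset`), and attribute `truth` (list: `active`, `betas`,
#'   `intercept`, `noise_sd`).
#' @export
make_recovery_suite <- function(count, base_spec = synthetic_spec()) {
  stopifnot(count >= 1, inherits(base_spec, "synthetic_spec"))
  seeds <- base_spec$seed + seq_len(count) - 1L
  datasets <- purrr::map(seeds, function(s) {
    sp <- base_spec
    sp$seed <- as.integer(s)
    simulate_qsar_dataset(sp)
  })
  out <- tibble(seed = seeds, dataset = datasets)
  attr(out, "truth") <- list(
    active = paste0("D", base_spec$active_set),
    betas = setNames(base_spec$betas, paste0("D", base_spec$active_set)),
    intercept = base_spec$intercept,
    noise_sd = base_spec$noise_sd
  )
  out
}
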
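#' Configuration for genetic-algorithm descriptor selection
#'
#' Defaults follow the selection protocol used for the bundled study:
#' population 800, 3000 generations, mutation rate 0.6, and a subset-size
#' cap of 4 (the largest published model in the bundled dataset uses four
#' descriptors). The mutation rate is interpreted per individual -- the
#' probability that an offspring undergoes one random bit flip -- since a
#' per-bit flip probability of 0.6 would randomise chromosomes faster than
#' selection could act.
#'
#' @param max_subset_size Largest descriptor subset considered (>= 1).
#' @param metric Fitness metric: `"q2"` (leave-one-out \eqn{Q^2}, the
#'   default) or `"r2"`.
#' @param population Number of chromosomes per generation.
#' @param generations Number of generations.
#' @param mutation_rate Per-individual probability of a single random bit
#'   flip, in \[0, 1\].
#' @param crossover_rate Probability that a parent pair recombines by
#'   uniform crossover (otherwise the parents are copied), in \[0, 1\].
#' @param elitism Number of best chromosomes copied unchanged into the next
#'   generation.
#' @param tournament_size Tournament size for parent selection.
#' @param seed Integer RNG seed; the whole GA trajectory is reproducible
#'   given the seed.
#' @param max_cor Optional pairwise-correlation guard: subsets containing a
#'   descriptor pair with |r| above this threshold are treated as
#'   infeasible. `NULL` (default) disables the guard.
#'
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(max_subset_size = 4, metric = c("q2", "r2"),
                             population = 800, generations = 3000,
                             mutation_rate = 0.6, crossover_rate = 0.9,
                             elitism = 1, tournament_size = 2, seed = 1,
                             max_cor = NULL) {
  metric <- match.arg(metric)
  stopifnot(
    max_subset_size >= 1, population >= 2, generations >= 1,
    mutation_rate >= 0, mutation_rate <= 1,
    crossover_rate >= 0, crossover_rate <= 1,
    elitism >= 0, tournament_size >= 1
  )
  structure(
    list(max_subset_size = as.integer(max_subset_size), metric = metric,
         population = as.integer(population), generations = as.integer(generations),
         mutation_rate = mutation_rate, crossover_rate = crossover_rate,
         elitism = as.integer(elitism), tournament_size = as.integer(tournament_size),
         seed = as.integer(seed), max_cor = max_cor),
    class = "selection_config"
  )
}

#' Evaluate one descriptor subset
#'
#' Fits OLS on the subset and attaches the full diagnostics; the subset's
#' fitness is the chosen metric (leave-one-out \eqn{Q^2} by default). When
#' `sentinel = TRUE` -- the mode used inside searches -- an infeasible
#' subset (rank deficient, or too large for the available degrees of
#' freedom) yields fitness `-Inf` instead of an error.
#'
#' @param dataset A `qsar_dataset`.
#' @param subset Character vector of descriptor names (non-empty).
#' @param metric `"q2"` or `"r2"`.
#' @param sentinel Return a `-Inf`-fitness record instead of erroring on
#'   infeasible subsets.
#'
#' @return An object of class `qsar_subset`: list with `descriptors`,
#'   `metric`, `fitness`, `model` (a `qsar_mlr`, or `NULL` if infeasible).
#' @examples
#' ds <- build_qsar_dataset(raf_descriptor_table(), "pIC50_RAF1")
#' evaluate_subset(ds, c("IW1", "FLEX"))$fitness # Q2 ~ 0.94
#' @export
evaluate_subset <- function(dataset, subset, metric = c("q2", "r2"),
                            sentinel = FALSE) {
  metric <- match.arg(metric)
  if (!length(subset)) abort("`subset` must name at least one descriptor.")
  unknown <- setdiff(subset, dataset$descriptor_names)
  if (length(unknown)) {
    abort(sprintf("Unknown descriptor(s): %s.", paste(unknown, collapse = ", ")))
  }
  res <- tryCatch(
    {
      model <- fit_mlr(dataset, descriptors = subset, loo = metric == "q2")
      if (metric == "q2" && is.null(model$loo)) {
        abort("Q2 fitness needs n >= p + 3.")
      }
      fitness <- if (metric == "q2") model$loo$q.squared else model$stats$r.squared
      list(model = model, fitness = fitness)
    },
    error = function(e) {
      if (sentinel) list(model = NULL, fitness = -Inf) else stop(e)
    }
  )
  structure(
    list(descriptors = subset, metric = metric,
         fitness = res$fitness, model = res$model),
    class = "qsar_subset"
  )
}

#' @export
print.qsar_subset <- function(x, ...) {
  cat(sprintf("<qsar_subset> {%s}: %s = %s\n",
              paste(x$descriptors, collapse = ", "), x$metric,
              format(x$fitness, digits = 4)))
  invisible(x)
}

# Lean per-subset evaluation used inside searches: no model object, no
# condition handling; returns NULL when the subset is infeasible (rank
# deficient or short of degrees of freedom). Computes the same quantities
# as fit_mlr()/loo_from_fit() by the same QR route.
fast_eval <- function(dataset, subset, need_loo = TRUE) {
  k <- length(subset)
  min_n <- if (need_loo) k + 3 else k + 2
  if (dataset$n < min_n) return(NULL)
  Xd <- cbind(1, dataset$X[, subset, drop = FALSE])
  f <- lm.fit(Xd, dataset$y, tol = 1e-10)
  if (f$rank < ncol(Xd)) return(NULL)
  res <- f$residuals
  rss <- sum(res^2)
  tss <- sum((dataset$y - mean(dataset$y))^2)
  out <- list(
    r.squared = 1 - rss / tss,
    sigma = sqrt(rss / (dataset$n - k - 1)),
    q.squared = NA_real_
  )
  if (need_loo) {
    h <- rowSums(qr.Q(f$qr)[, seq_len(f$rank), drop = FALSE]^2)
    if (any(h >= 1 - 1e-12)) return(NULL)
    out$q.squared <- 1 - sum((res / (1 - h))^2) / tss
  }
  out
}

# Fast fitness used inside searches: -Inf on any infeasibility.
subset_fitness <- function(dataset, subset, metric, max_cor = NULL) {
  if (!is.null(max_cor) && length(subset) > 1) {
    r <- stats::cor(dataset$X[, subset, drop = FALSE])
    if (max(abs(r[upper.tri(r)])) > max_cor) return(-Inf)
  }
  ev <- fast_eval(dataset, subset, need_loo = metric == "q2")
  if (is.null(ev)) return(-Inf)
  if (metric == "q2") ev$q.squared else ev$r.squared
}

#' Exhaustive (all-subsets) descriptor search
#'
#' Enumerates every descriptor subset of size 1 to `max_size`, fits each,
#' and returns the ranking: fitness descending, then smaller subsets first,
#' then lexicographic on the joined descriptor names -- a deterministic
#' total order. In the bundled study's protocol, all subsets were
#' enumerated for models of up to two descriptors, with the genetic
#' algorithm taking over beyond that.
#'
#' @param dataset A `qsar_dataset`.
#' @param max_size Largest subset size to enumerate.
#' @param metric `"q2"` or `"r2"`.
#' @param max_cor Optional pairwise-|r| feasibility guard (see
#'   [selection_config()]).
#' @param guard Maximum number of subsets to enumerate (default 1e6);
#'   exceeding it is an error suggesting [ga_search()].
#'
#' @return A tibble, one row per subset, columns `subset` (collapsed
#'   names), `descriptors` (list column), `size`, `fitness`, `r.squared`,
#'   `q.squared`, `sigma`, ranked best first.
#' @export
exhaustive_search <- function(dataset, max_size = 2, metric = c("q2", "r2"),
                              max_cor = NULL, guard = 1e6) {
  metric <- match.arg(metric)
  p <- dataset$p
  if (max_size > p) abort(sprintf("`max_size` (%d) exceeds the pool size (%d).", max_size, p))
  n_subsets <- sum(choose(p, seq_len(max_size)))
  if (n_subsets > guard) {
    abort(sprintf(
      "Exhaustive search over %.3g subsets exceeds the %.3g guard; use ga_search().",
      n_subsets, guard
    ))
  }
  subsets <- purrr::list_flatten(purrr::map(seq_len(max_size), function(k) {
    apply(combn(dataset$descriptor_names, k), 2, identity, simplify = FALSE)
  }))
  evals <- purrr::map(subsets, function(s) {
    ev <- fast_eval(dataset, s, need_loo = metric == "q2")
    if (is.null(ev)) return(c(-Inf, NA_real_, NA_real_, NA_real_))
    fitness <- if (metric == "q2") ev$q.squared else ev$r.squared
    if (!is.null(max_cor) && length(s) > 1) {
      r <- stats::cor(dataset$X[, s, drop = FALSE])
      if (max(abs(r[upper.tri(r)])) > max_cor) fitness <- -Inf
    }
    c(fitness, ev$r.squared, ev$q.squared, ev$sigma)
  })
  m <- do.call(rbind, evals)
  rows <- tibble(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    descriptors = subsets,
    size = lengths(subsets),
    fitness = m[, 1],
    r.squared = m[, 2],
    q.squared = m[, 3],
    sigma = m[, 4]
  )
  dplyr::arrange(rows, dplyr::desc(.data$fitness), .data$size, .data$subset)
}

#' Genetic-algorithm descriptor search
#'
#' Binary-mask chromosomes of length p, constrained to at most
#' `max_subset_size` active bits: generational loop with tournament parent
#' selection, uniform crossover, per-individual single-bit mutation,
#' elitism, and repair of constraint-violating offspring (random excess
#' bits are cleared; empty masks get one random bit). Fitness values are
#' memoised across the run, so the cost is bounded by the number of
#' distinct subsets visited. The best-ever subset is returned; the
#' trajectory is bit-identical for a given `config$seed`.
#'
#' @param dataset A `qsar_dataset` with at least two descriptors.
#' @param config A [selection_config()].
#'
#' @return A list of class `qsar_ga`: `best` (a `qsar_subset`), `history`
#'   (tibble: generation, best_fitness), `evaluations` (distinct subsets
#'   fitted), `config`.
#' @export
ga_search <- function(dataset, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  p <- dataset$p
  if (p < 2) abort("GA search needs a pool of at least 2 descriptors.")
  if (config$max_subset_size > p) {
    abort(sprintf("`max_subset_size` (%d) exceeds the pool size (%d).",
                  config$max_subset_size, p))
  }
  names_pool <- dataset$descriptor_names
  memo <- new.env(parent = emptyenv())
  fitness_of <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    f <- subset_fitness(dataset, names_pool[mask], config$metric, config$max_cor)
    memo[[key]] <- f
    f
  }
  repair <- function(mask) {
    k <- sum(mask)
    if (k > config$max_subset_size) {
      drop <- sample(which(mask), k - config$max_subset_size)
      mask[drop] <- FALSE
    } else if (k == 0) {
      mask[sample.int(p, 1)] <- TRUE
    }
    mask
  }

  result <- withr::with_seed(config$seed, {
    min_bits <- min(2L, config$max_subset_size)
    pop <- replicate(config$population, {
      k <- sample(seq(min_bits, config$max_subset_size), 1)
      mask <- logical(p)
      mask[sample.int(p, k)] <- TRUE
      mask
    }, simplify = FALSE)
    fit <- vapply(pop, fitness_of, numeric(1))
    best_mask <- pop[[which.max(fit)]]
    best_fit <- max(fit)
    history <- numeric(config$generations)

    for (gen in seq_len(config$generations)) {
      pick_parent <- function() {
        idx <- sample.int(config$population, config$tournament_size, replace = TRUE)
        pop[[idx[which.max(fit[idx])]]]
      }
      offspring <- vector("list", config$population)
      i <- 1L
      while (i <= config$population) {
        p1 <- pick_parent(); p2 <- pick_parent()
        if (stats::runif(1) < config$crossover_rate) {
          swap <- stats::runif(p) < 0.5
          c1 <- ifelse(swap, p2, p1)
          c2 <- ifelse(swap, p1, p2)
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (i > config$population) break
          if (stats::runif(1) < config$mutation_rate) {
            flip <- sample.int(p, 1)
            child[flip] <- !child[flip]
          }
          offspring[[i]] <- repair(child)
          i <- i + 1L
        }
      }
      if (config$elitism > 0) {
        elite_idx <- order(fit, decreasing = TRUE)[seq_len(min(config$elitism, config$population))]
        offspring[seq_along(elite_idx)] <- pop[elite_idx]
      }
      pop <- offspring
      fit <- vapply(pop, fitness_of, numeric(1))
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best_mask <- pop[[which.max(fit)]]
      }
      history[gen] <- best_fit
    }
    list(best_mask = best_mask, best_fit = best_fit, history = history)
  })

  if (!is.finite(result$best_fit)) {
    abort("No feasible subset found: every visited subset was rank deficient or df-infeasible.")
  }
  best <- evaluate_subset(dataset, names_pool[result$best_mask], config$metric)
  structure(
    list(
      best = best,
      history = tibble(generation = seq_len(config$generations),
                       best_fitness = result$history),
      evaluations = length(ls(memo)),
      config = config
    ),
    class = "qsar_ga"
  )
}

#' @export
print.qsar_ga <- function(x, ...) {
  cat(sprintf("<qsar_ga> best subset {%s}: %s = %s (%d distinct subsets fitted)\n",
              paste(x$best$descriptors, collapse = ", "), x$best$metric,
              format(x$best$fitness, digits = 4), x$evaluations))
  invisible(x)
}
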
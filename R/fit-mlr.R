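#' Fit an ordinary-least-squares QSAR model
#'
#' Fits pIC50 as a linear combination of molecular descriptors plus an
#' intercept, by QR least squares on the raw (unstandardised) descriptor
#' scales -- coefficients are therefore directly comparable with published
#' QSAR equations. Alongside the fit it computes the diagnostics
#' conventionally reported for small-n QSAR models:
#' \deqn{R^2 = 1 - RSS/TSS, \quad s = \sqrt{RSS/(n-p-1)}, \quad
#'       F = \frac{R^2/p}{(1-R^2)/(n-p-1)},}
#' and, when `loo = TRUE` and n >= p + 3, the leave-one-out
#' cross-validation summary (PRESS and \eqn{Q^2 = 1 - PRESS/TSS}, with TSS
#' taken about the mean of the full training response).
#'
#' @param data A `qsar_dataset` (from [build_qsar_dataset()] or
#'   [qsar_dataset()]) or a [descriptor_table] (in which case `response`
#'   is required).
#' @param response Response column name, used when `data` is a
#'   [descriptor_table].
#' @param descriptors Optional character vector restricting the fit to a
#'   descriptor subset.
#' @param loo Compute the leave-one-out summary (default `TRUE`).
#'
#' @return An object of class `qsar_mlr` with components `coefficients`
#'   (named, intercept first), `descriptor_names`, `n`, `p`, `ids`, `y`,
#'   `fitted`, `residuals`, `leverage`, `stats` (list: rss, tss, r.squared,
#'   sigma, fstatistic, p.value, rmse), and `loo` (list: heldout, press,
#'   q.squared, or `NULL`). Supports [tidy()], [glance()], [augment()],
#'   [predict()], [prediction_band()] and [ggplot2::autoplot()].
#'
#' @examples
#' ds <- build_qsar_dataset(raf_descriptor_table(), "pIC50_RAF1",
#'                          descriptors = c("IW1", "FLEX"))
#' fit <- fit_mlr(ds)
#' glance(fit)
#' @export
fit_mlr <- function(data, response = NULL, descriptors = NULL, loo = TRUE) {
  if (inherits(data, "descriptor_table")) {
    if (is.null(response)) abort("`response` is required when fitting a descriptor_table.")
    data <- build_qsar_dataset(data, response, descriptors)
  } else if (inherits(data, "qsar_dataset")) {
    if (!is.null(descriptors)) data <- subset_dataset(data, descriptors)
  } else {
    abort("`data` must be a qsar_dataset or a descriptor_table.")
  }
  n <- data$n; p <- data$p
  if (n < p + 2) {
    abort(sprintf("insufficient degrees of freedom: n = %d, p = %d (need n >= p + 2).", n, p))
  }
  Xd <- cbind(`(Intercept)` = 1, data$X)
  f <- lm.fit(Xd, data$y, tol = 1e-10)
  if (f$rank < ncol(Xd)) {
    aliased <- names(f$coefficients)[is.na(f$coefficients)]
    abort(sprintf("Design matrix is rank deficient; collinear column(s): %s.",
                  paste(aliased, collapse = ", ")))
  }
  coefs <- f$coefficients
  fitted <- as.numeric(Xd %*% coefs)
  res <- data$y - fitted
  rss <- sum(res^2)
  tss <- sum((data$y - mean(data$y))^2)
  r2 <- 1 - rss / tss
  df_res <- n - p - 1
  sigma <- sqrt(rss / df_res)
  fstat <- (r2 / p) / ((1 - r2) / df_res)
  pval <- stats::pf(fstat, p, df_res, lower.tail = FALSE)
  # leverages from the thin Q of the QR factorisation
  h <- rowSums(qr.Q(f$qr)[, seq_len(f$rank), drop = FALSE]^2)

  model <- structure(
    list(
      coefficients = coefs,
      descriptor_names = data$descriptor_names,
      response = data$response,
      n = n, p = p,
      ids = data$ids, y = data$y, X = data$X,
      fitted = fitted, residuals = res, leverage = h,
      qr = f$qr,
      stats = list(rss = rss, tss = tss, r.squared = r2, sigma = sigma,
                   fstatistic = fstat, p.value = pval, rmse = sqrt(rss / n)),
      loo = NULL
    ),
    class = "qsar_mlr"
  )
  if (loo && n >= p + 3) {
    model$loo <- loo_from_fit(model)
  }
  model
}

# Hat-matrix leave-one-out: e_i / (1 - h_ii) is the held-out residual.
loo_from_fit <- function(model) {
  h <- model$leverage
  if (any(h >= 1 - 1e-12)) {
    abort("Leave-one-out fold is rank deficient (leverage 1): a compound uniquely determines a coefficient.")
  }
  loo_resid <- model$residuals / (1 - h)
  heldout <- model$y - loo_resid
  press <- sum(loo_resid^2)
  list(
    heldout = tibble(compound = model$ids, observed = model$y,
                     predicted = heldout),
    press = press,
    q.squared = 1 - press / model$stats$tss
  )
}

#' Leave-one-out cross-validation of a descriptor subset
#'
#' Each compound is held out in turn, the model refitted on the remaining
#' n - 1, and the held-out compound predicted; the squared held-out errors
#' accumulate into PRESS and \eqn{Q^2 = 1 - PRESS/TSS} (TSS about the mean
#' of the full response). `method = "hat"` uses the algebraically exact
#' hat-matrix shortcut \eqn{e_i/(1-h_{ii})}; `method = "refit"` runs the
#' explicit n-fold refit loop. The two agree to machine precision and the
#' refit route exists as an internal cross-check.
#'
#' @inheritParams fit_mlr
#' @param method `"hat"` (default) or `"refit"`.
#' @return A list with `heldout` (tibble: compound, observed, predicted),
#'   `press` and `q.squared`.
#' @examples
#' ds <- build_qsar_dataset(raf_descriptor_table(), "pIC50_RAF1",
#'                          descriptors = c("IW1", "FLEX"))
#' loo_cv(ds)$q.squared
#' @export
loo_cv <- function(data, response = NULL, descriptors = NULL,
                   method = c("hat", "refit")) {
  method <- match.arg(method)
  if (inherits(data, "descriptor_table")) {
    data <- build_qsar_dataset(data, response, descriptors)
  } else if (inherits(data, "qsar_dataset") && !is.null(descriptors)) {
    data <- subset_dataset(data, descriptors)
  }
  if (!inherits(data, "qsar_dataset")) abort("`data` must be a qsar_dataset or descriptor_table.")
  if (data$n < data$p + 3) {
    abort(sprintf("Leave-one-out needs n >= p + 3 (each fold keeps n - 1 >= p + 2); n = %d, p = %d.",
                  data$n, data$p))
  }
  if (method == "hat") {
    model <- fit_mlr(data, loo = FALSE)
    return(loo_from_fit(model))
  }
  # explicit refit loop
  n <- data$n
  pred <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- cbind(1, data$X[-i, , drop = FALSE])
    fi <- lm.fit(Xi, data$y[-i], tol = 1e-10)
    if (fi$rank < ncol(Xi)) {
      abort(sprintf("Leave-one-out fold %d is rank deficient.", i))
    }
    pred[i] <- sum(c(1, data$X[i, ]) * fi$coefficients)
  }
  press <- sum((data$y - pred)^2)
  tss <- sum((data$y - mean(data$y))^2)
  list(
    heldout = tibble(compound = data$ids, observed = data$y, predicted = pred),
    press = press,
    q.squared = 1 - press / tss
  )
}

#' @export
print.qsar_mlr <- function(x, digits = 3, ...) {
  terms <- sprintf("%s x %s",
                   format(round(x$coefficients[-1], digits), trim = TRUE),
                   x$descriptor_names)
  eq <- paste(terms, collapse = " + ")
  cat(sprintf("<qsar_mlr> %s = %s + %s\n", x$response, eq,
              format(round(x$coefficients[1], digits), trim = TRUE)))
  cat(sprintf("  n = %d, R2 = %.3f, s = %.3f, F = %.2f", x$n,
              x$stats$r.squared, x$stats$sigma, x$stats$fstatistic))
  if (!is.null(x$loo)) cat(sprintf(", Q2(LOO) = %.3f", x$loo$q.squared))
  cat("\n")
  invisible(x)
}

#' Predict pIC50 for new descriptor rows
#'
#' @param object A `qsar_mlr` model.
#' @param newdata Data frame or matrix containing at least the model's
#'   descriptor columns. Defaults to the training data.
#' @param ... Unused.
#' @return Numeric vector of predicted pIC50s.
#' @export
predict.qsar_mlr <- function(object, newdata = NULL, ...) {
  X0 <- model_rows(object, newdata)
  as.numeric(cbind(1, X0) %*% object$coefficients)
}

model_rows <- function(object, newdata) {
  if (is.null(newdata)) return(object$X)
  if (is.data.frame(newdata) || is_tibble(newdata)) {
    missing_cols <- setdiff(object$descriptor_names, names(newdata))
    if (length(missing_cols)) {
      abort(sprintf("Missing descriptor column(s): %s.", paste(missing_cols, collapse = ", ")))
    }
    X0 <- as.matrix(newdata[object$descriptor_names])
  } else {
    X0 <- as.matrix(newdata)
    if (is.null(colnames(X0))) {
      if (ncol(X0) != object$p) abort("`newdata` must have one column per model descriptor.")
      colnames(X0) <- object$descriptor_names
    } else {
      missing_cols <- setdiff(object$descriptor_names, colnames(X0))
      if (length(missing_cols)) {
        abort(sprintf("Missing descriptor column(s): %s.", paste(missing_cols, collapse = ", ")))
      }
      X0 <- X0[, object$descriptor_names, drop = FALSE]
    }
  }
  storage.mode(X0) <- "double"
  X0
}

#' @export
tidy.qsar_mlr <- function(x, ...) {
  XtXinv <- xtx_inverse(x)
  se <- x$stats$sigma * sqrt(diag(XtXinv))
  stat <- x$coefficients / se
  df_res <- x$n - x$p - 1
  tibble(
    term = names(x$coefficients),
    estimate = as.numeric(x$coefficients),
    std.error = as.numeric(se),
    statistic = as.numeric(stat),
    p.value = 2 * pt(abs(stat), df_res, lower.tail = FALSE)
  )
}

#' @export
glance.qsar_mlr <- function(x, ...) {
  s <- x$stats
  df_res <- x$n - x$p - 1
  adj <- 1 - (1 - s$r.squared) * (x$n - 1) / df_res
  tibble(
    n = x$n, p = x$p,
    r.squared = s$r.squared, adj.r.squared = adj,
    sigma = s$sigma, statistic = s$fstatistic, p.value = s$p.value,
    rss = s$rss, tss = s$tss, rmse = s$rmse,
    press = if (is.null(x$loo)) NA_real_ else x$loo$press,
    q.squared = if (is.null(x$loo)) NA_real_ else x$loo$q.squared
  )
}

#' @export
augment.qsar_mlr <- function(x, ...) {
  out <- tibble(
    compound = x$ids,
    observed = x$y,
    .fitted = x$fitted,
    .resid = x$residuals,
    .hat = x$leverage
  )
  if (!is.null(x$loo)) {
    out$.loo_pred <- x$loo$heldout$predicted
    out$.loo_resid <- out$observed - out$.loo_pred
  }
  out
}

# (X'X)^{-1} on the original column order, from the stored QR factorisation.
xtx_inverse <- function(model) {
  R <- qr.R(model$qr)[seq_len(model$qr$rank), seq_len(model$qr$rank), drop = FALSE]
  inv <- chol2inv(R)
  piv <- model$qr$pivot[seq_len(model$qr$rank)]
  out <- matrix(NA_real_, nrow(inv), ncol(inv))
  out[piv, piv] <- inv
  dimnames(out) <- list(names(model$coefficients), names(model$coefficients))
  out
}

#' Serialise a fitted model to JSON
#'
#' Writes the descriptor names, coefficients, fit statistics, leave-one-out
#' summary and an MD5 fingerprint of the training data, so a downstream
#' consumer can verify which data produced which equation.
#'
#' @param model A `qsar_mlr`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  payload <- list(
    response = model$response,
    descriptors = model$descriptor_names,
    intercept = unname(model$coefficients[1]),
    coefficients = as.list(setNames(
      as.numeric(model$coefficients[-1]), model$descriptor_names
    )),
    n = model$n, p = model$p,
    stats = model$stats,
    loo = if (is.null(model$loo)) NULL else {
      list(press = model$loo$press, q.squared = model$loo$q.squared)
    },
    training_data_md5 = data_fingerprint(model)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

data_fingerprint <- function(model) {
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(list(model$ids, model$y, model$X), con, version = 2)
  close(con)
  unname(tools::md5sum(tmp))
}
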
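#' Confidence and prediction bands for a fitted QSAR model
#'
#' Classical OLS intervals with the t-distribution on n - p - 1 degrees of
#' freedom. For a descriptor row \eqn{x_0} the mean-response (confidence)
#' half-width is \eqn{t \cdot s\sqrt{x_0'(X'X)^{-1}x_0}} and the
#' new-observation (prediction) half-width is
#' \eqn{t \cdot s\sqrt{1 + x_0'(X'X)^{-1}x_0}}; the prediction band is
#' therefore strictly wider at every point whenever s > 0. These are the
#' bands conventionally drawn around experimental-versus-predicted QSAR
#' scatter plots.
#'
#' @param model A `qsar_mlr` fit.
#' @param newdata Descriptor rows to evaluate; training rows when omitted.
#' @param level Coverage probability in (0, 1); default 0.95.
#'
#' @return A tibble with columns `.fitted`, `conf_half_width`,
#'   `pred_half_width`, `conf_lwr`, `conf_upr`, `pred_lwr`, `pred_upr`, and
#'   (for training data) `compound` and `observed`. If the fit is exact
#'   (s = 0) all half-widths are zero and a warning is raised; the result
#'   then carries attribute `zero_width = TRUE`.
#' @export
prediction_band <- function(model, newdata = NULL, level = 0.95) {
  stopifnot(inherits(model, "qsar_mlr"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be a single probability strictly between 0 and 1.")
  }
  X0 <- model_rows(model, newdata)
  fitted0 <- as.numeric(cbind(1, X0) %*% model$coefficients)
  s <- model$stats$sigma
  # an interpolating fit leaves rounding-level residuals; treat s as zero
  # when it is negligible against the response's own scale
  zero_width <- s <= 1e-10 * max(sd(model$y), .Machine$double.xmin)
  if (zero_width) {
    warn("Residual standard error is zero (exact fit); returning zero-width bands.")
    hw_conf <- hw_pred <- rep(0, nrow(X0))
  } else {
    XtXinv <- xtx_inverse(model)
    Xd0 <- cbind(1, X0)
    # x0' (X'X)^{-1} x0 for each row
    v <- rowSums((Xd0 %*% XtXinv) * Xd0)
    tq <- qt(1 - (1 - level) / 2, df = model$n - model$p - 1)
    hw_conf <- tq * s * sqrt(v)
    hw_pred <- tq * s * sqrt(1 + v)
  }
  out <- tibble(
    .fitted = fitted0,
    conf_half_width = hw_conf,
    pred_half_width = hw_pred,
    conf_lwr = fitted0 - hw_conf, conf_upr = fitted0 + hw_conf,
    pred_lwr = fitted0 - hw_pred, pred_upr = fitted0 + hw_pred
  )
  if (is.null(newdata)) {
    out <- dplyr::bind_cols(tibble(compound = model$ids, observed = model$y), out)
  }
  attr(out, "level") <- level
  attr(out, "zero_width") <- zero_width
  out
}

#' Experimental-versus-predicted plot for a QSAR model
#'
#' Scatter of observed against fitted pIC50 with the regression identity
#' line and the `level` confidence (dashed green) and prediction (dashed
#' red) limits, the standard presentation of small-n QSAR fits.
#'
#' @param object A `qsar_mlr` fit.
#' @param level Band coverage probability.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qsar_mlr <- function(object, level = 0.95, ...) {
  band <- prediction_band(object, level = level)
  ord <- order(band$.fitted)
  band <- band[ord, ]
  ggplot2::ggplot(band, ggplot2::aes(x = .data$.fitted)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$pred_lwr, ymax = .data$pred_upr),
      fill = "red", alpha = 0.06
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$conf_lwr),
                       colour = "darkgreen", linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$conf_upr),
                       colour = "darkgreen", linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred_lwr),
                       colour = "red", linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred_upr),
                       colour = "red", linetype = "dashed") +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::labs(
      x = sprintf("Predicted %s", object$response),
      y = sprintf("Experimental %s", object$response),
      title = sprintf("Experimental vs predicted (%d%% confidence / prediction limits)",
                      round(level * 100))
    ) +
    ggplot2::theme_minimal()
}
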
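#' Forecast accuracy metrics
#'
#' The four metrics used throughout the pipeline:
#' \itemize{
#'   \item MAE = mean(|y - yhat|), in incidence units;
#'   \item MSE = mean((y - yhat)^2), in squared incidence units;
#'   \item MAPE = 100 * mean(|y - yhat| / |y|), in percent;
#'   \item Theil's U — by default the bounded U1 inequality coefficient
#'     `sqrt(mean((y - yhat)^2)) / (sqrt(mean(y^2)) + sqrt(mean(yhat^2)))`,
#'     which is 0 for a perfect forecast and at most 1. `variant = "u2"`
#'     gives the unbounded ratio `RMSE / sqrt(mean(y^2))` instead.
#' }
#' All four are zero exactly when the forecast is perfect. When any observed
#' value is zero, MAPE is reported as `NA` with a `mape_defined = FALSE` flag;
#' the other metrics are still computed.
#'
#' @param observed Numeric vector of observations.
#' @param predicted Aligned numeric vector of predictions.
#' @param theil_variant `"u1"` (default, bounded in `[0, 1]`) or `"u2"`.
#' @return Object of class `metric_set`: list with `mae`, `mse`, `mape`,
#'   `theil_u`, `mape_defined`, `n`.
#' @export
metrics <- function(observed, predicted, theil_variant = c("u1", "u2")) {
  theil_variant <- match.arg(theil_variant)
  stop_if(length(observed) != length(predicted),
          "metrics: observed and predicted must be aligned")
  stop_if(length(observed) < 1L, "metrics: need at least one point")
  stop_if(any(!is.finite(observed)) || any(!is.finite(predicted)),
          "metrics: inputs must be finite")
  e <- observed - predicted
  mae <- mean(abs(e))
  mse <- mean(e^2)
  mape_defined <- all(observed != 0)
  mape <- if (mape_defined) 100 * mean(abs(e) / abs(observed)) else NA_real_
  rmse <- sqrt(mse)
  denom <- switch(theil_variant,
                  u1 = sqrt(mean(observed^2)) + sqrt(mean(predicted^2)),
                  u2 = sqrt(mean(observed^2)))
  theil_u <- if (denom == 0) 0 else rmse / denom
  structure(list(mae = mae, mse = mse, mape = mape, theil_u = theil_u,
                 mape_defined = mape_defined, theil_variant = theil_variant,
                 n = length(observed)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("MAE %.4f | MSE %.4f | MAPE %s | Theil's U (%s) %.4f  [n = %d]\n",
              x$mae, x$mse,
              if (x$mape_defined) sprintf("%.4f%%", x$mape) else "undefined",
              x$theil_variant, x$theil_u, x$n))
  invisible(x)
}

#' @noRd
metric_row <- function(m) {
  data.frame(mae = m$mae, mse = m$mse, mape = m$mape, theil_u = m$theil_u)
}
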
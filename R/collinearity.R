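#' Multicollinearity diagnostics for the lag predictors
#'
#' Computes the Pearson correlation matrix of the ten lag columns, per-lag
#' variance inflation factors (VIF) and tolerances, and the eigenvalue
#' spectrum of the predictor correlation matrix with its condition indices
#' `sqrt(lambda_max / lambda_j)`. VIFs are obtained as the diagonal of the
#' inverse correlation matrix, which equals `1 / (1 - R2_j)` where `R2_j` is
#' the coefficient of determination from regressing predictor `j` on the other
#' nine with an intercept. VIF > 10 and condition index > 30 are flagged as
#' the conventional severe-collinearity thresholds.
#'
#' @param panel An `exposure_panel` with at least 12 rows (more rows than
#'   predictors) and no constant lag column.
#' @param include_intercept If `TRUE`, eigenvalues and condition indices are
#'   computed from the unit-length-scaled cross-product of the
#'   intercept-augmented design `[1 | X]` (11 values) instead of the 10x10
#'   predictor correlation matrix. The correlation-matrix convention is the
#'   default because it does not depend on an arbitrary intercept scaling.
#' @return Object of class `collinearity_report`: list with `correlation`
#'   (10x10 matrix), `vif`, `tolerance`, `eigenvalues` (descending),
#'   `condition_index`, `flag_vif` (VIF > 10), `flag_condition`
#'   (index > 30), `singular` (TRUE when a predictor is an exact linear
#'   combination of the others, in which case its VIF is `Inf`).
#' @export
diagnose_collinearity <- function(panel, include_intercept = FALSE) {
  validate_panel(panel)
  x <- lag_matrix(panel)
  n <- nrow(x)
  p <- ncol(x)
  stop_if(n < p + 2L, "diagnose_collinearity: need at least ", p + 2L, " rows")
  sds <- apply(x, 2, stats::sd)
  stop_if(any(sds == 0), "diagnose_collinearity: constant column(s): ",
          paste(colnames(x)[sds == 0], collapse = ", "))

  r <- stats::cor(x)
  singular <- FALSE
  vif <- tryCatch(diag(solve(r)), error = function(e) NULL)
  if (is.null(vif) || any(vif < 0)) {
    # exact linear dependence: fall back to per-column projections so the
    # dependent columns get VIF = Inf instead of an error
    singular <- TRUE
    xs <- scale(x)
    vif <- vapply(seq_len(p), function(j) {
      fit <- stats::lm.fit(cbind(1, xs[, -j, drop = FALSE]), xs[, j])
      r2 <- 1 - sum(fit$residuals^2) / sum((xs[, j] - mean(xs[, j]))^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  names(vif) <- colnames(x)

  if (include_intercept) {
    z <- cbind(intercept = 1, x)
    z <- sweep(z, 2, sqrt(colSums(z^2)), "/")   # unit column lengths
    ev <- eigen(crossprod(z), symmetric = TRUE, only.values = TRUE)$values
  } else {
    ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  }
  ev <- sort(pmax(ev, 0), decreasing = TRUE)
  ci <- sqrt(ev[1L] / ev)

  structure(list(
    correlation = r,
    vif = vif,
    tolerance = 1 / vif,
    eigenvalues = ev,
    condition_index = ci,
    flag_vif = vif > 10,
    flag_condition = ci > 30,
    singular = singular,
    include_intercept = include_intercept,
    n = n
  ), class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  cat("Collinearity diagnostics (", x$n, " rows, ", length(x$vif),
      " predictors)\n", sep = "")
  tab <- data.frame(VIF = round(x$vif, 2), tolerance = round(x$tolerance, 4),
                    severe = ifelse(x$flag_vif, "*", ""))
  print(tab)
  cat("eigenvalues:", paste(signif(x$eigenvalues, 3), collapse = " "), "\n")
  cat("condition indices:", paste(signif(x$condition_index, 4), collapse = " "), "\n")
  if (any(x$flag_condition)) {
    cat(sum(x$flag_condition), "condition indices exceed 30\n")
  }
  if (x$singular) cat("NOTE: exact linear dependence detected (VIF = Inf)\n")
  invisible(x)
}
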
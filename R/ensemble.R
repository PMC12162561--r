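#' Forecast error matrix of several models
#'
#' Stacks the per-model error series `e_i(t) = observed(t) - predicted_i(t)`
#' and forms the raw second-moment matrix `Omega_ij = mean_t(e_i(t) e_j(t))`.
#' Because Omega is not mean-centered, its diagonal equals each model's MSE
#' and the quadratic form `w' Omega w` equals the combined forecast's MSE for
#' any weights summing to 1.
#'
#' @param observed Numeric vector of observations.
#' @param predictions Named list of aligned prediction vectors, one per model.
#' @return Object of class `error_matrix`: `errors` (m x n matrix), `omega`
#'   (m x m), `models`, `n`.
#' @export
error_matrix <- function(observed, predictions) {
  stop_if(length(predictions) < 2L, "error_matrix: need at least 2 models")
  if (is.null(names(predictions)) || any(names(predictions) == "")) {
    names(predictions) <- paste0("model", seq_along(predictions))
  }
  n <- length(observed)
  stop_if(any(vapply(predictions, length, 1L) != n),
          "error_matrix: prediction series misaligned with observations")
  e <- t(vapply(predictions, function(p) observed - p, numeric(n)))
  omega <- tcrossprod(e) / n
  structure(list(errors = e, omega = omega,
                 models = names(predictions), n = n),
            class = "error_matrix")
}

#' Combination-forecast weights
#'
#' Three classical schemes for weighting `m` forecasts from their error
#' moment matrix `Omega`:
#' \describe{
#'   \item{std_dev}{`w_i = (S - S_i) / ((m - 1) S)` with `S_i = sqrt(Omega_ii)`
#'     (root mean squared error of model `i`) and `S = sum_j S_j`; nonnegative
#'     by construction.}
#'   \item{inv_variance}{`w_i = Omega_ii^{-1} / sum_j Omega_jj^{-1}`;
#'     a model with zero MSE receives the full weight, with a warning.}
#'   \item{optimal}{`w = Omega^{-1} 1 / (1' Omega^{-1} 1)`, the minimizer of
#'     the combined in-sample MSE `w' Omega w` subject to `sum(w) = 1`;
#'     weights may be negative. If `Omega` is singular (or
#'     `nonnegative = TRUE`), the minimizer over the probability simplex is
#'     found by dense grid search at step 1e-3 instead, with a warning in the
#'     singular case.}
#' }
#'
#' @param errors An [error_matrix()].
#' @param method `"std_dev"`, `"inv_variance"` or `"optimal"`.
#' @param nonnegative For `"optimal"`, restrict the weights to the simplex.
#' @return Object of class `ensemble_weights`: `method`, named `weights`
#'   summing to 1, and the achieved combined MSE `w' Omega w`.
#' @export
compute_weights <- function(errors,
                            method = c("std_dev", "inv_variance", "optimal"),
                            nonnegative = FALSE) {
  stop_if(!inherits(errors, "error_matrix"), "errors must be an error_matrix")
  method <- match.arg(method)
  omega <- errors$omega
  m <- nrow(omega)
  stop_if(method == "optimal" && errors$n < m,
          "compute_weights: optimal weighting needs n >= number of models")

  w <- switch(method,
    std_dev = {
      s <- sqrt(diag(omega))
      if (all(s == 0)) rep(1 / m, m) else (sum(s) - s) / ((m - 1) * sum(s))
    },
    inv_variance = {
      v <- diag(omega)
      if (any(v == 0)) {
        warning("compute_weights: a model has zero MSE; it receives weight 1",
                call. = FALSE)
        as.numeric(seq_len(m) == which(v == 0)[1L])
      } else {
        (1 / v) / sum(1 / v)
      }
    },
    optimal = {
      if (diff(range(omega)) <= 1e-14 * max(abs(omega), 1)) {
        # identical error series: every weighting is optimal; by symmetry,
        # return equal weights
        return(structure(list(method = method,
                              weights = stats::setNames(rep(1 / m, m),
                                                        errors$models),
                              combined_mse = mean(omega)),
                         class = "ensemble_weights"))
      }
      sol <- if (nonnegative) NULL else
        tryCatch(solve(omega, rep(1, m)), error = function(e) NULL)
      if (is.null(sol)) {
        if (!nonnegative) {
          warning("compute_weights: singular error moment matrix; ",
                  "falling back to simplex grid search", call. = FALSE)
        }
        simplex_grid_search(omega, step = 1e-3)
      } else {
        sol / sum(sol)
      }
    }
  )
  names(w) <- errors$models
  structure(list(method = method, weights = w,
                 combined_mse = drop(t(w) %*% omega %*% w)),
            class = "ensemble_weights")
}

#' Exhaustive minimizer of w' Omega w over the probability simplex.
#'
#' Enumerates the first m-1 coordinates on a regular grid; used as the
#' fallback optimal-weight solver and as the oracle the closed form is
#' checked against.
#' @noRd
simplex_grid_search <- function(omega, step = 1e-3) {
  m <- nrow(omega)
  g <- seq(0, 1, by = step)
  if (m == 2L) {
    w_all <- cbind(g, 1 - g)
  } else if (m == 3L) {
    grid <- expand.grid(w1 = g, w2 = g)
    grid <- grid[grid$w1 + grid$w2 <= 1 + 1e-12, ]
    w_all <- cbind(grid$w1, grid$w2, pmax(1 - grid$w1 - grid$w2, 0))
  } else {
    stop("simplex grid search implemented for 2 or 3 models", call. = FALSE)
  }
  q <- rowSums((w_all %*% omega) * w_all)
  # ties (e.g. identical models) are broken toward equal weights
  cand <- which(q <= min(q) + 1e-12)
  if (length(cand) > 1L) {
    cand <- cand[which.min(rowSums((w_all[cand, , drop = FALSE] - 1 / m)^2))]
  }
  unname(w_all[cand[1L], ])
}

#' @export
print.ensemble_weights <- function(x, ...) {
  cat(sprintf("Combination weights (%s): %s  [combined MSE %.4f]\n",
              x$method,
              paste(sprintf("%s = %.4f", names(x$weights), x$weights),
                    collapse = ", "),
              x$combined_mse))
  invisible(x)
}

#' Combined forecast
#'
#' `combined(t) = sum_i w_i * predicted_i(t)`. Because the weights sum to 1,
#' the combined error is the same weighted average of the single-model errors.
#'
#' @param predictions Named list of aligned prediction vectors (same models,
#'   same order as the weights).
#' @param weights An [compute_weights()] result.
#' @return Numeric vector of combined predictions.
#' @export
combine_predictions <- function(predictions, weights) {
  stop_if(!inherits(weights, "ensemble_weights"), "weights must be ensemble_weights")
  stop_if(length(predictions) != length(weights$weights),
          "combine_predictions: one prediction series per weight required")
  n <- unique(vapply(predictions, length, 1L))
  stop_if(length(n) != 1L, "combine_predictions: prediction series misaligned")
  if (!is.null(names(predictions))) {
    stop_if(!identical(sort(names(predictions)), sort(names(weights$weights))),
            "combine_predictions: model names do not match the weights")
    predictions <- predictions[names(weights$weights)]
  }
  drop(Reduce(`+`, Map(`*`, predictions, as.list(weights$weights))))
}
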
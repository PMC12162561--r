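#' Ridge regression on standardized predictors
#'
#' Fits `beta = (X'X + kI)^{-1} X'y` on standardized predictors and response
#' (zero mean, unit variance), back-transforms for prediction on the original
#' incidence scale, and reports the ridge-adjusted variance inflation factors
#' `VIF_j(k) = [(X'X + kI)^{-1} X'X (X'X + kI)^{-1}]_jj * (n - 1)`, which
#' reduce to the ordinary VIFs at `k = 0`. The ridge parameter `k` is on the
#' scale of the standardized cross-product `X'X = (n - 1) R` and is therefore
#' sample-size dependent; it is a tuning input, typically chosen from a ridge
#' trace ([ridge_trace()]).
#'
#' @param panel An `exposure_panel` (>= 12 rows).
#' @param incidence Aligned `incidence_series`.
#' @param k Ridge penalty, finite and >= 0. `k = 0` is ordinary least squares.
#' @return Object of class `ridge_fit`: `k`, `coef_std` (standardized
#'   coefficients), `coef` and `intercept` on the original scale,
#'   `modified_vif`, `fitted` (original scale), `mse_std` (in-sample MSE of
#'   the standardized fit), `r2`, and `metrics` (a [metrics()] set on the
#'   original scale).
#' @export
ridge_fit <- function(panel, incidence, k = 0) {
  validate_panel(panel)
  y <- align_incidence(panel, incidence)
  stop_if(!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0,
          "ridge_fit: k must be a single finite value >= 0")
  x <- lag_matrix(panel)
  n <- nrow(x)
  stop_if(n < ncol(x) + 2L, "ridge_fit: need at least ", ncol(x) + 2L, " rows")
  stop_if(stats::var(y) == 0, "ridge_fit: response has zero variance")

  mx <- colMeans(x); sx <- apply(x, 2, stats::sd)
  my <- mean(y);     sy <- stats::sd(y)
  stop_if(any(sx == 0), "ridge_fit: constant predictor column")
  xs <- sweep(sweep(x, 2, mx), 2, sx, "/")
  ys <- (y - my) / sy

  sxx <- crossprod(xs)
  a <- solve(sxx + diag(k, ncol(xs)))
  b_std <- drop(a %*% crossprod(xs, ys))
  vif_k <- diag(a %*% sxx %*% a) * (n - 1)
  names(b_std) <- names(vif_k) <- colnames(x)

  fitted_std <- drop(xs %*% b_std)
  fitted <- my + sy * fitted_std
  coef <- b_std * sy / sx
  intercept <- my - sum(coef * mx)
  m <- metrics(y, fitted)

  structure(list(k = k, coef_std = b_std, coef = coef, intercept = intercept,
                 modified_vif = vif_k, fitted = fitted,
                 mse_std = mean((ys - fitted_std)^2),
                 r2 = 1 - m$mse / pop_var(y), metrics = m, n = n),
            class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf("Ridge regression (k = %g, n = %d): R^2 = %.4f, max modified VIF = %.2f\n",
              x$k, x$n, x$r2, max(x$modified_vif)))
  print(x$metrics)
  invisible(x)
}

#' Ridge trace over a penalty grid
#'
#' Refits [ridge_fit()] at each `k` and collects the standardized coefficient
#' paths, in-sample MSE (standardized and original scale) and modified VIFs.
#' On the training data the standardized MSE is non-decreasing in `k` and the
#' coefficient norm non-increasing — the trace is used to pick the smallest
#' `k` at which the coefficients have stabilized.
#'
#' @inheritParams ridge_fit
#' @param k_grid Positive, ascending penalty grid (an unsorted grid is sorted
#'   with a warning).
#' @return Object of class `ridge_trace`: `k`, `coef_std` (length(k) x 10
#'   matrix), `mse_std`, `mse`, `vif` (length(k) x 10 matrix of modified
#'   VIFs), `coef_norm`.
#' @export
ridge_trace <- function(panel, incidence, k_grid) {
  stop_if(length(k_grid) < 1L, "ridge_trace: empty k grid")
  stop_if(any(!is.finite(k_grid)) || any(k_grid < 0),
          "ridge_trace: k values must be finite and >= 0")
  if (is.unsorted(k_grid)) {
    warning("ridge_trace: unsorted k grid; sorting ascending", call. = FALSE)
    k_grid <- sort(k_grid)
  }
  fits <- lapply(k_grid, function(k) ridge_fit(panel, incidence, k))
  coef_std <- t(vapply(fits, function(f) f$coef_std, numeric(10)))
  vif <- t(vapply(fits, function(f) f$modified_vif, numeric(10)))
  structure(list(k = k_grid, coef_std = coef_std,
                 mse_std = vapply(fits, function(f) f$mse_std, numeric(1)),
                 mse = vapply(fits, function(f) f$metrics$mse, numeric(1)),
                 vif = vif,
                 coef_norm = sqrt(rowSums(coef_std^2))),
            class = "ridge_trace")
}

#' @export
print.ridge_trace <- function(x, ...) {
  cat("Ridge trace over", length(x$k), "penalties\n")
  print(data.frame(k = x$k, coef_norm = round(x$coef_norm, 4),
                   mse_std = round(x$mse_std, 6),
                   max_vif = round(apply(x$vif, 1, max), 3)))
  invisible(x)
}

#' Support-vector regression with kernel selection
#'
#' Fits epsilon-insensitive SVR with each candidate kernel on standardized
#' inputs, compares in-sample MSE and `R^2 = 1 - MSE / var(y)`, and returns
#' the kernel with minimal MSE (ties broken by higher R^2, then by kernel
#' list order).
#'
#' @inheritParams ridge_fit
#' @param kernels Candidate kernels among `"linear"`, `"sigmoid"`, `"rbf"`,
#'   `"polynomial"`.
#' @param cost Regularization strength (default 1).
#' @param epsilon Insensitivity tube width on the standardized response
#'   (default 0.1).
#' @param gamma Kernel bandwidth for rbf/sigmoid/polynomial; default
#'   `1 / (10 * v)` with `v` the (unit) variance of the standardized features.
#' @param degree Polynomial degree (default 3).
#' @return Object of class `svr_fit`: selected `kernel`, the fitted `model`,
#'   `comparison` (per-kernel MSE and R^2 table), `fitted`, `mse`, `r2`,
#'   `metrics`.
#' @export
svr_select <- function(panel, incidence,
                       kernels = c("linear", "sigmoid", "rbf", "polynomial"),
                       cost = 1, epsilon = 0.1, gamma = NULL, degree = 3) {
  validate_panel(panel)
  y <- align_incidence(panel, incidence)
  stop_if(nrow(panel) < 12L, "svr_select: need at least 12 rows")
  stop_if(stats::var(y) == 0, "svr_select: response has zero variance")
  kernels <- match.arg(kernels, several.ok = TRUE)
  if (is.null(gamma)) gamma <- 1 / 10   # standardized features have unit variance
  dat <- as.data.frame(lag_matrix(panel))
  vy <- pop_var(y)

  fit_one <- function(kern) {
    e1071_kern <- if (kern == "rbf") "radial" else kern
    model <- e1071::svm(x = dat, y = y, type = "eps-regression",
                        kernel = e1071_kern, cost = cost, epsilon = epsilon,
                        gamma = gamma, degree = degree, scale = TRUE)
    fitted <- as.numeric(stats::predict(model, dat))
    mse <- mean((y - fitted)^2)
    list(kernel = kern, model = model, fitted = fitted,
         mse = mse, r2 = 1 - mse / vy)
  }
  all_fits <- lapply(kernels, fit_one)
  comparison <- data.frame(kernel = kernels,
                           mse = vapply(all_fits, function(f) f$mse, numeric(1)),
                           r2 = vapply(all_fits, function(f) f$r2, numeric(1)),
                           stringsAsFactors = FALSE)
  best_mse <- min(comparison$mse)
  cand <- which(comparison$mse == best_mse)
  if (length(cand) > 1L) cand <- cand[which.max(comparison$r2[cand])]
  best <- all_fits[[cand[1L]]]

  structure(list(kernel = best$kernel, model = best$model,
                 comparison = comparison, fitted = best$fitted,
                 mse = best$mse, r2 = best$r2,
                 metrics = metrics(y, best$fitted),
                 data = dat, observed = y,
                 hyper = list(cost = cost, epsilon = epsilon, gamma = gamma,
                              degree = degree)),
            class = "svr_fit")
}

#' @export
print.svr_fit <- function(x, ...) {
  cat("SVR kernel comparison (in-sample):\n")
  print(transform(x$comparison, mse = round(mse, 4), r2 = round(r2, 4)))
  cat(sprintf("selected kernel: %s (MSE %.4f, R^2 %.4f)\n", x$kernel, x$mse, x$r2))
  invisible(x)
}

#' Permutation feature importance for a fitted SVR
#'
#' `score_j` is the mean increase in in-sample MSE when lag column `j` is
#' randomly permuted (breaking its link with the response) while all other
#' columns are left intact, averaged over `n_repeats` permutations.
#' Deterministic given `seed`. Used because a kernel SVR has no native
#' coefficients.
#'
#' @param fit An `svr_fit` trained on this panel.
#' @param panel The `exposure_panel` the fit was trained on.
#' @param incidence Aligned `incidence_series`.
#' @param n_repeats Number of permutations per column (>= 1).
#' @param seed Integer seed for the permutations.
#' @return data.frame of class `feature_importance` with columns `lag` and
#'   `importance` (MSE increase), in lag0..lag9 order.
#' @export
feature_importance <- function(fit, panel, incidence, n_repeats = 10L,
                               seed = 1L) {
  stop_if(!inherits(fit, "svr_fit"), "fit must be an svr_fit")
  stop_if(n_repeats < 1L, "feature_importance: n_repeats must be >= 1")
  validate_panel(panel)
  y <- align_incidence(panel, incidence)
  dat <- as.data.frame(lag_matrix(panel))
  base_mse <- mean((y - as.numeric(stats::predict(fit$model, dat)))^2)
  set.seed(as.integer(seed))
  scores <- vapply(seq_along(LAG_COLS), function(j) {
    mean(vapply(seq_len(n_repeats), function(rep) {
      perm <- dat
      perm[[j]] <- perm[[j]][sample.int(nrow(perm))]
      mean((y - as.numeric(stats::predict(fit$model, perm)))^2) - base_mse
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(lag = LAG_COLS, importance = scores,
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_importance", "data.frame")
  out
}

# ---- small feed-forward network (10 -> h -> h -> h -> 1, ReLU) --------------

#' He-style initialization of one layer set for the given sizes.
#' @noRd
mlp_init <- function(sizes) {
  n_layers <- length(sizes) - 1L
  w <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    w[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L]) * sqrt(2 / sizes[l]),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(w = w, b = b)
}

#' @noRd
mlp_forward <- function(par, x) {
  n_layers <- length(par$w)
  a <- vector("list", n_layers + 1L)
  a[[1L]] <- x
  for (l in seq_len(n_layers)) {
    z <- sweep(a[[l]] %*% par$w[[l]], 2, par$b[[l]], "+")
    a[[l + 1L]] <- if (l < n_layers) pmax(z, 0) else z   # ReLU hidden, linear out
  }
  a
}

#' @noRd
mlp_predict <- function(par, x) {
  drop(mlp_forward(par, x)[[length(par$w) + 1L]])
}

#' Full-batch Adam training of the MLP on an MSE loss. Returns NULL when the
#' loss goes non-finite.
#' @noRd
mlp_train <- function(x, y, hidden, epochs, learning_rate) {
  sizes <- c(ncol(x), hidden, 1L)
  par <- mlp_init(sizes)
  n_layers <- length(par$w)
  m_w <- lapply(par$w, function(w) w * 0); v_w <- m_w
  m_b <- lapply(par$b, function(b) b * 0); v_b <- m_b
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  n <- nrow(x)

  for (epoch in seq_len(epochs)) {
    a <- mlp_forward(par, x)
    out <- drop(a[[n_layers + 1L]])
    if (!all(is.finite(out))) return(NULL)
    delta <- matrix(2 * (out - y) / n, ncol = 1L)
    for (l in n_layers:1) {
      gw <- crossprod(a[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(par$w[[l]])) * (a[[l]] > 0)
      }
      m_w[[l]] <- beta1 * m_w[[l]] + (1 - beta1) * gw
      v_w[[l]] <- beta2 * v_w[[l]] + (1 - beta2) * gw^2
      m_b[[l]] <- beta1 * m_b[[l]] + (1 - beta1) * gb
      v_b[[l]] <- beta2 * v_b[[l]] + (1 - beta2) * gb^2
      corr1 <- 1 - beta1^epoch; corr2 <- 1 - beta2^epoch
      par$w[[l]] <- par$w[[l]] - learning_rate * (m_w[[l]] / corr1) /
        (sqrt(v_w[[l]] / corr2) + adam_eps)
      par$b[[l]] <- par$b[[l]] - learning_rate * (m_b[[l]] / corr1) /
        (sqrt(v_b[[l]] / corr2) + adam_eps)
    }
  }
  par
}

#' Feed-forward network with hidden-node tuning
#'
#' Trains a 10 -> h -> h -> h -> 1 network with ReLU hidden activations and a
#' linear output on standardized inputs and response, for every candidate node
#' count `h`, using full-batch Adam for a fixed epoch budget. The node count
#' with the smallest hold-out MSE is selected and the network refit on all
#' rows. The same `h` is used in all three hidden layers. Deterministic given
#' `seed` and the training configuration.
#'
#' @inheritParams ridge_fit
#' @param node_grid Candidate hidden-layer node counts (default 5..20).
#' @param seed Integer seed (hold-out split and weight initialization).
#' @param epochs Training epochs per candidate (default 2000).
#' @param learning_rate Adam step size (default 0.01).
#' @param holdout_fraction Fraction of rows held out for node selection
#'   (default 0.2).
#' @return Object of class `network_fit`: `node_grid`, `val_mse` (named
#'   hold-out MSE per h, standardized scale; `Inf` for candidates whose
#'   training diverged), `selected_h`, `fitted` (original scale), `r2`,
#'   `metrics`, and the trained parameters with their scaling.
#' @export
network_fit <- function(panel, incidence, node_grid = 5:20, seed = 1L,
                        epochs = 2000L, learning_rate = 0.01,
                        holdout_fraction = 0.2) {
  validate_panel(panel)
  y <- align_incidence(panel, incidence)
  x <- lag_matrix(panel)
  n <- nrow(x)
  stop_if(n < 12L, "network_fit: need at least 12 rows")
  stop_if(length(node_grid) < 1L || any(node_grid < 1),
          "network_fit: node_grid must be positive node counts")
  stop_if(holdout_fraction <= 0 || holdout_fraction >= 1,
          "network_fit: holdout_fraction must be in (0, 1)")
  stop_if(stats::var(y) == 0, "network_fit: response has zero variance")

  mx <- colMeans(x); sx <- apply(x, 2, stats::sd)
  my <- mean(y);     sy <- stats::sd(y)
  xs <- sweep(sweep(x, 2, mx), 2, sx, "/")
  ys <- (y - my) / sy

  set.seed(as.integer(seed))
  n_val <- max(1L, round(holdout_fraction * n))
  stop_if(n_val >= n, "network_fit: hold-out leaves no training rows")
  val_idx <- sample.int(n, n_val)

  val_mse <- stats::setNames(rep(Inf, length(node_grid)),
                             paste0("h", node_grid))
  for (i in seq_along(node_grid)) {
    h <- node_grid[i]
    set.seed(as.integer(seed) + h)
    par <- mlp_train(xs[-val_idx, , drop = FALSE], ys[-val_idx],
                     rep(h, 3L), epochs, learning_rate)
    if (is.null(par)) {
      warning("network_fit: training diverged at h = ", h,
              "; candidate skipped", call. = FALSE)
      next
    }
    pred <- mlp_predict(par, xs[val_idx, , drop = FALSE])
    if (all(is.finite(pred))) val_mse[i] <- mean((ys[val_idx] - pred)^2)
  }
  stop_if(all(!is.finite(val_mse)), "network_fit: training diverged at every node count")
  selected_h <- node_grid[which.min(val_mse)]

  set.seed(as.integer(seed) + selected_h)
  par <- mlp_train(xs, ys, rep(selected_h, 3L), epochs, learning_rate)
  stop_if(is.null(par), "network_fit: refit at the selected node count diverged")
  fitted <- my + sy * mlp_predict(par, xs)
  m <- metrics(y, fitted)

  structure(list(node_grid = node_grid, val_mse = val_mse,
                 selected_h = selected_h, fitted = fitted,
                 r2 = 1 - m$mse / pop_var(y), metrics = m,
                 parameters = par,
                 scaling = list(mx = mx, sx = sx, my = my, sy = sy),
                 seed = as.integer(seed), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 holdout_fraction = holdout_fraction, n = n),
            class = "network_fit")
}

#' @export
print.network_fit <- function(x, ...) {
  cat(sprintf("Feed-forward network 10 -> %d -> %d -> %d -> 1 (ReLU), n = %d\n",
              x$selected_h, x$selected_h, x$selected_h, x$n))
  cat(sprintf("selected h = %d of grid [%s]; R^2 = %.4f\n", x$selected_h,
              paste(range(x$node_grid), collapse = "-"), x$r2))
  print(x$metrics)
  invisible(x)
}

#' @export
predict.network_fit <- function(object, panel, ...) {
  validate_panel(panel)
  x <- lag_matrix(panel)
  xs <- sweep(sweep(x, 2, object$scaling$mx), 2, object$scaling$sx, "/")
  object$scaling$my + object$scaling$sy * mlp_predict(object$parameters, xs)
}
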
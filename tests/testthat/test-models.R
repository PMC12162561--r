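# ---- ridge ------------------------------------------------------------------

test_that("ridge at k = 0 reproduces ordinary least squares", {
  s <- synth_panel(seed = 20, n_regions = 30, n_years = 5, ar_rho = 0.6)
  rf <- ridge_fit(s$panel, s$incidence, k = 0)
  ols <- lm(s$incidence$incidence ~ as.matrix(s$panel[, paste0("lag", 0:9)]))
  expect_equal(unname(rf$coef), unname(coef(ols)[-1]), tolerance = 1e-8)
  expect_equal(rf$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
})

test_that("extreme shrinkage drives the standardized coefficients to zero", {
  s <- synth_panel(seed = 20)
  rf <- ridge_fit(s$panel, s$incidence, k = 1e9)
  expect_lt(sqrt(sum(rf$coef_std^2)), 1e-3)
})

test_that("ridge solution matches an independent dense linear solve", {
  s <- synth_panel(seed = 22, n_regions = 20, n_years = 5)
  k <- 100
  rf <- ridge_fit(s$panel, s$incidence, k = k)
  # oracle: re-derive the standardized system from scratch
  x <- as.matrix(s$panel[, paste0("lag", 0:9)])
  y <- s$incidence$incidence
  xs <- scale(x); ys <- as.numeric(scale(y))
  beta <- solve(t(xs) %*% xs + k * diag(10), t(xs) %*% ys)
  expect_equal(unname(rf$coef_std), as.numeric(beta), tolerance = 1e-8)
})

test_that("modified VIF at k = 0 equals the ordinary VIF", {
  s <- synth_panel(seed = 23)
  rf <- ridge_fit(s$panel, s$incidence, k = 0)
  d <- diagnose_collinearity(s$panel)
  expect_equal(rf$modified_vif, d$vif, tolerance = 1e-6)
})

test_that("ridge trace: MSE non-decreasing, coefficient norm non-increasing", {
  s <- synth_panel(seed = 24)
  tr <- ridge_trace(s$panel, s$incidence, c(0, 1, 10, 100, 1000))
  expect_true(all(diff(tr$mse_std) >= -1e-12))
  expect_true(all(diff(tr$coef_norm) <= 1e-12))
  # max modified VIF shrinks from the smallest to the largest k
  expect_lte(max(tr$vif[nrow(tr$vif), ]), max(tr$vif[1, ]))
})

test_that("singleton trace equals the single fit; unsorted grids warn", {
  s <- synth_panel(seed = 24)
  tr <- ridge_trace(s$panel, s$incidence, 0)
  rf <- ridge_fit(s$panel, s$incidence, 0)
  expect_equal(as.numeric(tr$coef_std[1, ]), unname(rf$coef_std))
  expect_equal(tr$mse_std[1], rf$mse_std)
  expect_warning(ridge_trace(s$panel, s$incidence, c(10, 1)), "unsorted")
  expect_error(ridge_fit(s$panel, s$incidence, k = -1), "k must")
})

test_that("low-noise ridge at small k recovers the generating lag weights", {
  ok <- 0L
  for (seed in 1:20) {
    cfg0 <- synth_config(seed = seed, n_regions = 500, noise_sd = 0)
    gen <- generate_panel(cfg0)
    signal_sd <- sd(generate_incidence(gen$panel, cfg0)$incidence)
    cfg <- synth_config(seed = seed, n_regions = 500,
                        noise_sd = 0.05 * signal_sd)
    inc <- generate_incidence(gen$panel, cfg)
    rf <- ridge_fit(gen$panel, inc, k = 0.1)
    rel <- sqrt(sum((rf$coef - cfg$lag_weights)^2) / sum(cfg$lag_weights^2))
    if (rel < 0.10) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

# ---- SVR --------------------------------------------------------------------

test_that("an exactly linear response is fit nearly perfectly", {
  s <- synth_panel(seed = 30, noise_sd = 0, ar_rho = 0.5)
  fit <- svr_select(s$panel, s$incidence, epsilon = 0.001, cost = 100)
  expect_gt(fit$r2, 0.99)
})

test_that("the R^2 / MSE identity holds for every kernel", {
  s <- synth_panel(seed = 31)
  fit <- svr_select(s$panel, s$incidence)
  y <- s$incidence$incidence
  vy <- mean((y - mean(y))^2)
  expect_equal(fit$comparison$r2, 1 - fit$comparison$mse / vy,
               tolerance = 1e-10)
  expect_equal(nrow(fit$comparison), 4)
})

test_that("a radial pattern is captured better by the rbf kernel than linear", {
  s <- synth_panel(seed = 32, n_regions = 40, n_years = 4, ar_rho = 0.3)
  p <- s$panel
  center <- colMeans(as.matrix(p[, c("lag2", "lag6")]))
  rad <- sqrt((p$lag2 - center[1])^2 + (p$lag6 - center[2])^2)
  y <- incidence_for(p, 50 + 10 * exp(-(rad / 8)^2))
  fit <- svr_select(p, y, kernels = c("linear", "rbf"))
  cmp <- fit$comparison
  expect_lt(cmp$mse[cmp$kernel == "rbf"], cmp$mse[cmp$kernel == "linear"])
  expect_identical(fit$kernel, "rbf")
  expect_error(svr_select(p, incidence_for(p, rep(5, nrow(p)))), "zero variance")
})

test_that("permutation importance is maximal for the only informative lag", {
  s <- synth_panel(seed = 33, noise_sd = 0, ar_rho = 0.2,
                   lag_weights = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0),
                   intercept = 0)
  fit <- svr_select(s$panel, s$incidence, kernels = "rbf")
  imp <- feature_importance(fit, s$panel, s$incidence, n_repeats = 5, seed = 2)
  expect_identical(imp$lag[which.max(imp$importance)], "lag4")
  # determinism
  imp2 <- feature_importance(fit, s$panel, s$incidence, n_repeats = 5, seed = 2)
  expect_identical(imp, imp2)
  expect_error(feature_importance(fit, s$panel, s$incidence, n_repeats = 0),
               "n_repeats")
})

test_that("permuting a constant column scores exactly zero", {
  set.seed(34)
  x <- matrix(50 + rnorm(40 * 10, sd = 6), 40, 10)
  x[, 6] <- 42   # lag5 constant
  p <- panel_from_matrix(x)
  y <- incidence_for(p, 10 + 0.5 * x[, 1] + rnorm(40, sd = 0.5))
  fit <- suppressWarnings(svr_select(p, y, kernels = "rbf"))  # constant column cannot be scaled
  imp <- feature_importance(fit, p, y, n_repeats = 3, seed = 1)
  expect_equal(imp$importance[imp$lag == "lag5"], 0)
})

test_that("permutation importance ordering matches a leave-one-feature-out oracle", {
  set.seed(35)
  x <- matrix(50 + rnorm(60 * 10, sd = 6), 60, 10)
  p <- panel_from_matrix(x)
  # two informative features with very different additive effect sizes
  y_vec <- 10 + 2.0 * x[, 1] + 0.4 * x[, 2] + rnorm(60, sd = 0.5)
  y <- incidence_for(p, y_vec)
  fit <- svr_select(p, y, kernels = "rbf")
  imp <- feature_importance(fit, p, y, n_repeats = 10, seed = 3)
  # oracle: refit without each informative feature, measure the MSE increase
  lofo <- vapply(1:2, function(j) {
    m <- e1071::svm(x = as.data.frame(x[, -j]), y = y_vec,
                    type = "eps-regression", kernel = "radial",
                    cost = 1, epsilon = 0.1, gamma = 0.1, scale = TRUE)
    mean((y_vec - predict(m, as.data.frame(x[, -j])))^2)
  }, numeric(1))
  expect_gt(lofo[1], lofo[2])                       # dropping lag0 hurts more
  expect_gt(imp$importance[1], imp$importance[2])   # same ordering
})

# ---- network ----------------------------------------------------------------

test_that("a noise-free linear response is learned to within 5% on most rows", {
  s <- synth_panel(seed = 36, noise_sd = 0, n_regions = 30, n_years = 5)
  fit <- network_fit(s$panel, s$incidence, node_grid = 8, seed = 11,
                     epochs = 1500)
  rel_err <- abs(fit$fitted - s$incidence$incidence) / s$incidence$incidence
  expect_gte(mean(rel_err < 0.05), 0.90)
})

test_that("a singleton node grid is selected trivially and runs are deterministic", {
  s <- synth_panel(seed = 37, n_regions = 15, n_years = 3)
  a <- network_fit(s$panel, s$incidence, node_grid = 7, seed = 5, epochs = 200)
  expect_equal(a$selected_h, 7)
  b <- network_fit(s$panel, s$incidence, node_grid = 7, seed = 5, epochs = 200)
  expect_identical(a$fitted, b$fitted)
  expect_identical(a$selected_h, b$selected_h)
})

test_that("the selected node count minimizes hold-out MSE over the grid", {
  s <- synth_panel(seed = 38, n_regions = 20, n_years = 4)
  fit <- network_fit(s$panel, s$incidence, node_grid = c(5, 9, 13), seed = 3,
                     epochs = 300)
  expect_equal(fit$selected_h,
               fit$node_grid[which.min(fit$val_mse)])
  expect_length(fit$val_mse, 3)
  # predict() on the training panel reproduces the stored fit
  expect_equal(predict(fit, s$panel), fit$fitted, tolerance = 1e-12)
})
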
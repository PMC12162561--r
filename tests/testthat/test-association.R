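test_that("normality test matches the reference Shapiro-Wilk implementation", {
  x <- c(148, 154, 158, 160, 161, 162, 166, 170, 182, 195, 236)
  nt <- normality_test(x)
  ref <- stats::shapiro.test(x)
  expect_equal(nt$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(nt$p_value, ref$p.value, tolerance = 1e-10)
  expect_lt(abs(nt$statistic - 0.79), 0.01)
  expect_lt(nt$p_value, 0.05)

  set.seed(99)
  g <- rnorm(500)
  expect_gt(normality_test(g)$p_value, 0.05)
  set.seed(99)
  e <- rexp(50)
  expect_lt(normality_test(e)$p_value, 0.01)

  expect_error(normality_test(c(1, 2)), "at least 3")
  expect_error(normality_test(rep(5, 10)), "zero variance")
  expect_error(normality_test(c(1, 2, NA, 4)), "finite")
})

test_that("perfect linear dependence gives coefficient +/- 1 at the right lag", {
  s <- synth_panel(seed = 4, noise_sd = 0,
                   lag_weights = c(rep(0, 9), 1), intercept = 0)
  a <- lag_correlation(s$panel, s$incidence)
  expect_equal(a$coefficient[a$lag == "lag9"], 1, tolerance = 1e-10)

  neg <- incidence_for(s$panel, 200 - s$panel$lag0)
  a2 <- lag_correlation(s$panel, neg)
  expect_equal(a2$coefficient[a2$lag == "lag0"], -1, tolerance = 1e-10)
})

test_that("Pearson coefficient equals the textbook sum formula on a hand panel", {
  set.seed(21)
  x <- matrix(50 + rnorm(50, sd = 4), 5, 10)
  x[, 1] <- c(10, 12, 15, 16, 18)
  p <- panel_from_matrix(x)
  y <- c(20, 24, 25, 30, 33)
  a <- lag_correlation(p, incidence_for(p, y))
  # direct sum-formula oracle for lag0
  xl <- x[, 1]; n <- 5
  r_hand <- (n * sum(xl * y) - sum(xl) * sum(y)) /
    sqrt((n * sum(xl^2) - sum(xl)^2) * (n * sum(y^2) - sum(y)^2))
  row0 <- a[a$lag == "lag0", ]
  expect_identical(row0$method, "pearson")
  expect_equal(row0$coefficient, r_hand, tolerance = 1e-12)
})

test_that("the normality gate selects Pearson iff both p-values exceed alpha", {
  s <- synth_panel(seed = 17, n_regions = 40, n_years = 3, noise_sd = 3)
  for (alpha in c(0.05, 0.5, 0.99)) {
    a <- lag_correlation(s$panel, s$incidence, alpha = alpha)
    gate <- a$normality_p_exposure > alpha & a$normality_p_incidence > alpha
    expect_identical(a$method, ifelse(gate, "pearson", "spearman"))
    expect_true(all(abs(a$coefficient) <= 1))
    expect_true(all(a$p_value >= 0 & a$p_value <= 1))
  }
})

test_that("misaligned keys are rejected", {
  s <- synth_panel(seed = 1, n_regions = 6, n_years = 2)
  wrong <- s$incidence
  wrong$year <- wrong$year + 100L
  expect_error(lag_correlation(s$panel, wrong), "misaligned")
})

test_that("grey relational degree is 1 for self-comparison and matches the hand oracle", {
  ref <- c(1, 2, 3)
  self <- grey_relational(ref, list(same = ref))
  expect_equal(unname(self$degrees), 1)

  # hand oracle for ref (1,2,3) vs (3,2,1), rho = 0.5, mean normalization:
  # ref* = (0.5, 1, 1.5), comp* = (1.5, 1, 0.5), delta = (1, 0, 1),
  # dmin = 0, dmax = 1, xi = (1/3, 1, 1/3), degree = 5/9
  g <- grey_relational(ref, list(rev = c(3, 2, 1)), rho = 0.5,
                       normalization = "mean")
  expect_equal(unname(g$degrees), 5 / 9, tolerance = 1e-10)
})

test_that("grey relational degrees respect the resolution-coefficient bound", {
  set.seed(31)
  for (i in 1:20) {
    ref <- runif(8, 1, 10)
    comps <- lapply(1:4, function(j) runif(8, 1, 10))
    g <- grey_relational(ref, comps, rho = 0.5)
    expect_true(all(g$degrees > 1 / 3))
    expect_true(all(g$degrees <= 1))
  }
})

test_that("mean-normalized GRA is invariant to a common positive rescaling", {
  set.seed(32)
  ref <- runif(10, 5, 15)
  comps <- list(a = runif(10, 5, 15), b = runif(10, 5, 15))
  g1 <- grey_relational(ref, comps, normalization = "mean")
  g2 <- grey_relational(7.3 * ref, lapply(comps, `*`, 7.3),
                        normalization = "mean")
  expect_equal(g1$degrees, g2$degrees, tolerance = 1e-12)
})

test_that("GRA input validation and degenerate cases behave as specified", {
  expect_error(grey_relational(c(-1, 1), list(a = c(1, 2))), "zero-mean")
  expect_error(grey_relational(c(1), list(a = c(1))), "length >= 2")
  expect_error(grey_relational(c(1, 2), list(a = c(1, 2, 3))), "length")
  # all series identical -> dmax = 0 -> all degrees 1
  g <- grey_relational(c(2, 4), list(a = c(2, 4), b = c(2, 4)))
  expect_equal(unname(g$degrees), c(1, 1))
})

test_that("grouped GRA table has one degree per (lag, year) plus overall", {
  s <- synth_panel(seed = 9, n_regions = 10, n_years = 3)
  tab <- grey_relational_table(s$panel, s$incidence)
  expect_setequal(unique(tab$group), c("2014", "2015", "2016", "overall"))
  expect_equal(nrow(tab), 10 * 4)
  expect_true(all(tab$degree > 1 / 3 & tab$degree <= 1))
})

test_that("a dominant lag weight is detected as the strongest correlation", {
  hits <- 0L
  for (seed in 1:50) {
    s <- synth_panel(seed = seed, n_regions = 60, n_years = 1, ar_rho = 0.7,
                     lag_weights = c(rep(0, 9), 0.5), intercept = 10,
                     noise_sd = 0.3)   # ~5% of the lag9 signal sd (0.5 * 12)
    a <- lag_correlation(s$panel, s$incidence)
    if (which.max(abs(a$coefficient)) == 10L) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})
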
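#' Shapiro-Wilk normality test
#'
#' Thin, validated wrapper used as the gate that decides between Pearson and
#' Spearman correlation in [lag_correlation()].
#'
#' @param x Numeric sample, `n >= 3`, finite, not all identical.
#' @return list with `statistic` (the W statistic) and `p_value`.
#' @export
normality_test <- function(x) {
  stop_if(!is.numeric(x) || length(x) < 3L, "normality_test: need at least 3 values")
  stop_if(any(!is.finite(x)), "normality_test: values must be finite")
  stop_if(stats::var(x) == 0, "normality_test: sample has zero variance")
  sw <- stats::shapiro.test(x)
  list(statistic = unname(sw$statistic), p_value = sw$p.value)
}

#' Normality-gated per-lag correlation
#'
#' For each lag column, tests both the exposure column and the incidence
#' series for normality (Shapiro-Wilk); when both p-values exceed `alpha` the
#' Pearson product-moment correlation is used, otherwise the Spearman rank
#' correlation. P-values are two-sided and uncorrected.
#'
#' @param panel An `exposure_panel`.
#' @param incidence An aligned `incidence_series`.
#' @param alpha Normality-gate significance level (default 0.05).
#' @return A data.frame of class `lag_association` with one row per lag:
#'   `lag`, `method`, `coefficient`, `p_value`, `normality_p_exposure`,
#'   `normality_p_incidence`.
#' @export
lag_correlation <- function(panel, incidence, alpha = 0.05) {
  validate_panel(panel)
  y <- align_incidence(panel, incidence)
  stop_if(nrow(panel) < 4L, "lag_correlation: need at least 4 rows")
  p_inc <- normality_test(y)$p_value
  x <- lag_matrix(panel)
  rows <- lapply(0:9, function(L) {
    xl <- x[, L + 1L]
    p_exp <- normality_test(xl)$p_value
    method <- if (p_exp > alpha && p_inc > alpha) "pearson" else "spearman"
    ct <- suppressWarnings(
      stats::cor.test(xl, y, method = method, alternative = "two.sided",
                      exact = FALSE))
    data.frame(lag = paste0("lag", L), method = method,
               coefficient = unname(ct$estimate), p_value = ct$p.value,
               normality_p_exposure = p_exp, normality_p_incidence = p_inc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lag_association", "data.frame")
  out
}

#' @noRd
gra_normalize <- function(x, normalization) {
  switch(normalization,
    mean = {
      stop_if(mean(x) == 0, "grey_relational: zero-mean series under mean normalization")
      x / mean(x)
    },
    initial = {
      stop_if(x[1L] == 0, "grey_relational: zero initial value under initial normalization")
      x / x[1L]
    },
    minmax = {
      rng <- range(x)
      stop_if(rng[1L] == rng[2L], "grey_relational: constant series under minmax normalization")
      (x - rng[1L]) / (rng[2L] - rng[1L])
    },
    stop("unknown normalization: ", normalization, call. = FALSE)
  )
}

#' Grey relational analysis (Deng's relational degree)
#'
#' Measures how closely each comparison series tracks the reference series.
#' After normalizing every series, pointwise absolute deviations
#' `D_i(t) = |ref*(t) - comp_i*(t)|` are formed, and the relational
#' coefficient is `xi_i(t) = (Dmin + rho * Dmax) / (D_i(t) + rho * Dmax)`
#' with `Dmin`/`Dmax` taken globally over all comparisons and points. The
#' relational degree is the arithmetic mean of `xi_i(t)` over `t`; it lies in
#' `(rho/(1+rho), 1]` and equals 1 exactly when the comparison matches the
#' reference after normalization.
#'
#' @param reference Numeric reference series, length >= 2.
#' @param comparisons A named list of numeric series (or a matrix whose
#'   columns are series) of the same length as `reference`.
#' @param rho Resolution coefficient in `(0, 1]`; conventional default 0.5.
#' @param normalization One of `"mean"` (divide by the series mean),
#'   `"initial"` (divide by the first value), `"minmax"` (rescale to `[0,1]`).
#' @return Object of class `grey_relational`: list with `rho`,
#'   `normalization`, `degrees` (named vector) and the coefficient matrix.
#' @export
grey_relational <- function(reference, comparisons, rho = 0.5,
                            normalization = c("mean", "initial", "minmax")) {
  normalization <- match.arg(normalization)
  stop_if(!is.numeric(rho) || rho <= 0 || rho > 1, "rho must be in (0, 1]")
  if (is.matrix(comparisons)) {
    comparisons <- lapply(seq_len(ncol(comparisons)),
                          function(j) comparisons[, j])
  }
  stop_if(length(comparisons) < 1L, "need at least one comparison series")
  if (is.null(names(comparisons)) || any(names(comparisons) == "")) {
    names(comparisons) <- paste0("series", seq_along(comparisons))
  }
  n <- length(reference)
  stop_if(n < 2L, "series must have length >= 2")
  stop_if(any(vapply(comparisons, length, 1L) != n),
          "all comparison series must match the reference length")

  ref_n <- gra_normalize(reference, normalization)
  comp_n <- vapply(comparisons, gra_normalize, numeric(n),
                   normalization = normalization)
  delta <- abs(comp_n - ref_n)          # n x m matrix of deviations
  dmin <- min(delta)
  dmax <- max(delta)
  if (dmax == 0) {                       # all series identical to the reference
    xi <- matrix(1, n, length(comparisons))
  } else {
    xi <- (dmin + rho * dmax) / (delta + rho * dmax)
  }
  degrees <- colMeans(xi)
  names(degrees) <- names(comparisons)
  structure(list(rho = rho, normalization = normalization,
                 degrees = degrees, coefficients = xi),
            class = "grey_relational")
}

#' @export
print.grey_relational <- function(x, ...) {
  cat(sprintf("Grey relational analysis (rho = %g, %s normalization)\n",
              x$rho, x$normalization))
  print(round(sort(x$degrees, decreasing = TRUE), 4))
  invisible(x)
}

#' Grey relational degrees of each lag, per year and overall
#'
#' For each outcome year, the incidence rates across regions form the
#' reference series and each lag column the comparison series; the pooled
#' "overall" group uses all region-years at once. This yields one relational
#' degree per (lag, group) cell.
#'
#' @inheritParams lag_correlation
#' @inheritParams grey_relational
#' @return A tidy data.frame of class `grey_relational_table` with columns
#'   `lag`, `group` (year or `"overall"`) and `degree`.
#' @export
grey_relational_table <- function(panel, incidence, rho = 0.5,
                                  normalization = "mean") {
  validate_panel(panel)
  y <- align_incidence(panel, incidence)
  x <- lag_matrix(panel)
  groups <- c(as.character(sort(unique(panel$year))), "overall")
  rows <- lapply(groups, function(g) {
    sel <- if (g == "overall") rep(TRUE, nrow(panel)) else panel$year == as.integer(g)
    stop_if(sum(sel) < 2L, "grey_relational_table: group ", g, " has < 2 rows")
    gra <- grey_relational(y[sel],
                           as.list(as.data.frame(x[sel, , drop = FALSE])),
                           rho = rho, normalization = normalization)
    data.frame(lag = LAG_COLS, group = g, degree = unname(gra$degrees),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("grey_relational_table", "data.frame")
  out
}
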
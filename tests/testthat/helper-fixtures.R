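# Shared fixtures, built in code at test time.

# Wrap a numeric matrix (rows = region-years, 10 columns) as an exposure_panel;
# one synthetic region per row so keys are trivially unique.
panel_from_matrix <- function(x) {
  colnames(x) <- paste0("lag", 0:9)
  p <- data.frame(region_id = sprintf("R%04d", seq_len(nrow(x))),
                  year = 2014L, x, stringsAsFactors = FALSE)
  class(p) <- c("exposure_panel", "data.frame")
  p
}

incidence_for <- function(panel, values) {
  out <- data.frame(region_id = panel$region_id, year = panel$year,
                    incidence = values, stringsAsFactors = FALSE)
  class(out) <- c("incidence_series", "data.frame")
  out
}

# A positive panel whose 10 columns are exactly uncorrelated (empirical
# correlation = identity), for orthogonal-design diagnostics.
uncorrelated_panel <- function(n = 60, seed = 11) {
  set.seed(seed)
  x <- matrix(rnorm(n * 10), n, 10)
  x <- scale(x, scale = FALSE)
  x <- x %*% solve(chol(crossprod(x) / (n - 1)))   # whiten: unit, uncorrelated
  panel_from_matrix(x * 3 + 50)
}

# Default small synthetic panel + incidence under one seed.
synth_panel <- function(seed = 1, n_regions = 30, n_years = 5, ...) {
  cfg <- synth_config(seed = seed, n_regions = n_regions, n_years = n_years, ...)
  gen <- generate_panel(cfg)
  list(cfg = cfg, panel = gen$panel, truth = gen$truth,
       incidence = generate_incidence(gen$panel, cfg))
}
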
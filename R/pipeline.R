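#' Pipeline configuration
#'
#' Describes one end-to-end run: the input panel (a CSV on disk or a
#' [synth_config()] block — exactly one of the two), the analysis parameters
#' of every stage, an optional output directory, and one global seed from
#' which every stochastic stage (synthetic generation, network training,
#' permutation importance) derives its own sub-stream. When a synth block is
#' given, its seed is overridden by the sub-seed derived from the pipeline
#' seed so that the global seed alone determines the run.
#'
#' @param input_csv Path to a `region_id, year, lag0..lag9, incidence` CSV.
#' @param synth A [synth_config()] for a synthetic run.
#' @param alpha Normality-gate level for [lag_correlation()].
#' @param gra_rho,gra_normalization Grey-relational parameters.
#' @param ridge_k Ridge penalty for the reported fit.
#' @param ridge_k_grid Penalty grid for the ridge trace.
#' @param svr_kernels,svr_cost,svr_epsilon SVR candidates and hyperparameters.
#' @param node_grid,epochs,learning_rate,holdout_fraction Network training.
#' @param importance_repeats Permutation-importance repeats.
#' @param ensemble_methods Weighting schemes to apply.
#' @param nonnegative_weights Restrict optimal weights to the simplex.
#' @param outdir Output directory for the report and CSV tables (`NULL` for
#'   in-memory only).
#' @param seed Global integer seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_csv = NULL, synth = NULL,
                            alpha = 0.05,
                            gra_rho = 0.5, gra_normalization = "mean",
                            ridge_k = 100, ridge_k_grid = c(0, 1, 10, 100, 1000),
                            svr_kernels = c("linear", "sigmoid", "rbf", "polynomial"),
                            svr_cost = 1, svr_epsilon = 0.1,
                            node_grid = 5:20, epochs = 2000L,
                            learning_rate = 0.01, holdout_fraction = 0.2,
                            importance_repeats = 10L,
                            ensemble_methods = c("std_dev", "inv_variance", "optimal"),
                            nonnegative_weights = FALSE,
                            outdir = NULL, seed = 1L) {
  stop_if(is.null(input_csv) == is.null(synth),
          "pipeline_config: exactly one of input_csv or synth must be given")
  stop_if(!is.null(synth) && !inherits(synth, "synth_config"),
          "pipeline_config: synth must be a synth_config")
  structure(list(input_csv = input_csv, synth = synth, alpha = alpha,
                 gra_rho = gra_rho, gra_normalization = gra_normalization,
                 ridge_k = ridge_k, ridge_k_grid = ridge_k_grid,
                 svr_kernels = svr_kernels, svr_cost = svr_cost,
                 svr_epsilon = svr_epsilon,
                 node_grid = node_grid, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 holdout_fraction = holdout_fraction,
                 importance_repeats = as.integer(importance_repeats),
                 ensemble_methods = ensemble_methods,
                 nonnegative_weights = isTRUE(nonnegative_weights),
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline config from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `synth:` mapping
#' is passed to [synth_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  stop_if(!file.exists(path), "no such config file: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synth)) raw$synth <- do.call(synth_config, raw$synth)
  do.call(pipeline_config, raw)
}

#' @noRd
config_hash <- function(config) {
  plain <- unclass(config)
  plain$outdir <- NULL              # where outputs land is not analysis config
  plain$synth <- if (!is.null(plain$synth)) unclass(plain$synth)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Sequences: panel acquisition (synthetic or CSV) -> per-lag association and
#' grey relational analysis -> collinearity diagnostics -> ridge trace and
#' ridge fit, SVR kernel selection with permutation importance, network fit ->
#' error-matrix ensemble under the configured weighting schemes -> metric
#' table (3 single models + one row per combination scheme). When
#' `config$outdir` is set, writes `report.json`, `table1_gra.csv`,
#' `lag_correlation.csv`, `collinearity.csv`, `predictions_<model>.csv` and
#' `table2_metrics.csv` there. The run is deterministic given the config:
#' repeating it yields a byte-identical report.
#'
#' @param config A [pipeline_config()].
#' @return The report, a nested list, invisibly.
#' @export
run_pipeline <- function(config) {
  stop_if(!inherits(config, "pipeline_config"), "config must be a pipeline_config")
  sub <- derive_seeds(config$seed, 3L)

  if (!is.null(config$synth)) {
    log_msg("stage synth: generating ", config$synth$n_regions, " x ",
            config$synth$n_years, " panel")
    scfg <- config$synth
    scfg$seed <- sub[1L] %% 2147483647L
    class(scfg) <- "synth_config"
    gen <- generate_panel(scfg)
    panel <- gen$panel
    incidence <- generate_incidence(panel, scfg)
  } else {
    log_msg("stage input: reading ", config$input_csv)
    dat <- read_panel_csv(config$input_csv)
    panel <- dat$panel
    incidence <- dat$incidence
  }
  y <- align_incidence(panel, incidence)

  log_msg("stage association")
  assoc <- lag_correlation(panel, incidence, alpha = config$alpha)
  gra <- grey_relational_table(panel, incidence, rho = config$gra_rho,
                               normalization = config$gra_normalization)

  log_msg("stage collinearity")
  collin <- diagnose_collinearity(panel)

  log_msg("stage models: ridge (k = ", config$ridge_k, ")")
  trace <- ridge_trace(panel, incidence, config$ridge_k_grid)
  ridge <- ridge_fit(panel, incidence, k = config$ridge_k)

  log_msg("stage models: SVR kernel selection")
  svr <- svr_select(panel, incidence, kernels = config$svr_kernels,
                    cost = config$svr_cost, epsilon = config$svr_epsilon)
  importance <- feature_importance(svr, panel, incidence,
                                   n_repeats = config$importance_repeats,
                                   seed = sub[3L] %% 2147483647L)

  log_msg("stage models: network (grid ", min(config$node_grid), "-",
          max(config$node_grid), ")")
  network <- network_fit(panel, incidence, node_grid = config$node_grid,
                         seed = sub[2L] %% 2147483647L,
                         epochs = config$epochs,
                         learning_rate = config$learning_rate,
                         holdout_fraction = config$holdout_fraction)

  log_msg("stage ensemble")
  predictions <- list(ridge = ridge$fitted, svr = svr$fitted,
                      network = network$fitted)
  errs <- error_matrix(y, predictions)
  combos <- lapply(config$ensemble_methods, function(meth) {
    w <- compute_weights(errs, method = meth,
                         nonnegative = config$nonnegative_weights && meth == "optimal")
    pred <- combine_predictions(predictions, w)
    list(method = meth, weights = as.list(w$weights),
         metrics = unclass(metrics(y, pred)), predictions = pred)
  })
  names(combos) <- config$ensemble_methods

  single_metrics <- list(ridge = ridge$metrics, svr = svr$metrics,
                         network = network$metrics)
  table2 <- rbind(
    do.call(rbind, lapply(names(single_metrics), function(nm)
      cbind(model = nm, metric_row(single_metrics[[nm]])))),
    do.call(rbind, lapply(names(combos), function(nm)
      cbind(model = paste0("combined_", nm),
            metric_row(structure(combos[[nm]]$metrics, class = "metric_set")))))
  )

  report <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    n_rows = nrow(panel),
    input = if (is.null(config$input_csv)) "synthetic" else config$input_csv,
    association = as.data.frame(assoc),
    grey_relational = as.data.frame(gra),
    collinearity = list(
      vif = as.list(collin$vif),
      tolerance = as.list(collin$tolerance),
      eigenvalues = collin$eigenvalues,
      condition_index = collin$condition_index,
      n_vif_gt_10 = sum(collin$flag_vif),
      n_condition_gt_30 = sum(collin$flag_condition)
    ),
    models = list(
      ridge = list(k = ridge$k, coef_std = as.list(ridge$coef_std),
                   coef = as.list(ridge$coef), intercept = ridge$intercept,
                   modified_vif = as.list(ridge$modified_vif), r2 = ridge$r2,
                   metrics = unclass(ridge$metrics),
                   trace = list(k = trace$k, mse_std = trace$mse_std,
                                coef_norm = trace$coef_norm)),
      svr = list(kernel = svr$kernel, comparison = svr$comparison,
                 r2 = svr$r2, metrics = unclass(svr$metrics),
                 hyper = svr$hyper,
                 importance = as.data.frame(importance)),
      network = list(node_grid = network$node_grid,
                     val_mse = as.list(network$val_mse),
                     selected_h = network$selected_h, r2 = network$r2,
                     metrics = unclass(network$metrics))
    ),
    ensemble = lapply(combos, function(cb) cb[c("method", "weights", "metrics")]),
    table2 = table2
  )

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_outputs(config$outdir, report, panel, y, predictions, combos,
                  gra, assoc, collin)
  }
  log_msg("pipeline complete (", nrow(panel), " region-years)")
  invisible(report)
}

#' @noRd
write_outputs <- function(outdir, report, panel, y, predictions, combos,
                          gra, assoc, collin) {
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null", na = "null")
  # table1_gra.csv: lags as rows, one column per year plus overall
  wide <- stats::reshape(as.data.frame(gra), idvar = "lag", timevar = "group",
                         direction = "wide")
  names(wide) <- sub("^degree\\.", "", names(wide))
  utils::write.csv(wide[rev(seq_len(nrow(wide))), ],
                   file.path(outdir, "table1_gra.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(assoc),
                   file.path(outdir, "lag_correlation.csv"), row.names = FALSE)
  utils::write.csv(data.frame(lag = rownames(collin$correlation),
                              round(collin$correlation, 6),
                              vif = collin$vif, tolerance = collin$tolerance),
                   file.path(outdir, "collinearity.csv"), row.names = FALSE)
  for (nm in names(predictions)) {
    pred <- predictions[[nm]]
    utils::write.csv(data.frame(region_id = panel$region_id, year = panel$year,
                                observed = y, predicted = pred,
                                relative_error = ifelse(y == 0, NA,
                                                        (pred - y) / y)),
                     file.path(outdir, paste0("predictions_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(report$table2, file.path(outdir, "table2_metrics.csv"),
                   row.names = FALSE)
  invisible(outdir)
}
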
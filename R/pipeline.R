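#' Derive a stage seed from the master seed
#'
#' Every stochastic stage of [run_pipeline()] draws its seed from the master
#' seed by hashing the stage name (sum of UTF-8 codes) into a 31-bit
#' integer, so any stage can be rerun in isolation with the same seed it
#' received inside the full run.
#'
#' @param master Integer master seed.
#' @param stage Stage name, e.g. `"simulate"`, `"importance"`, `"fit"`,
#'   `"forecast"`.
#' @return An integer seed in `[1, 2^31 - 1]`.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage)) %% 1000L
  as.integer((abs(as.numeric(master)) * 131 + h * 7 + 1) %% 2147483647)
}

#' Run the full cold-stun analysis pipeline
#'
#' Executes the stages in order — window search, covariate assembly,
#' two-stage permutation-importance screening, DIC backward selection of
#' the Bayesian negative-binomial errors-in-variables count model, and the
#' warming-trend forecast — either on supplied data tables or on a
#' synthetic scenario. Exactly one of the two input modes must be used.
#' Every stochastic stage derives its seed from `seed` via [stage_seed()],
#' so a run is fully reproducible from `(inputs, seed)`.
#'
#' @param strandings,sst,hatchlings Input tibbles (see [read_strandings()],
#'   [read_daily_sst()], [read_hatchlings()]); `NULL` when `scenario` is
#'   given.
#' @param nao,amo Optional monthly climate-index tibbles.
#' @param scenario A [scenario_params()] object; its `seed` field is
#'   replaced by `stage_seed(seed, "simulate")`.
#' @param max_open,min_length Window-search bounds (days before 31 Dec).
#' @param n_trees,collinearity_threshold Importance-screen settings.
#' @param negligible Negligibility bound for backward selection.
#' @param n_chains,n_adapt,n_burn,n_iter,thin,strict MCMC settings (see
#'   [fit_nb_eiv()]).
#' @param trend_last_n,horizon,forecast_error_sd Forecast settings.
#' @param assume A [population_assumptions()] object for the impact figure.
#' @param seed Master seed.
#' @param out_dir Optional directory: when given, every stage table and a
#'   machine-readable `summary.json` are written there.
#' @return A list of class `"coldstun_run"` with elements `windows`,
#'   `covariate_table`, `screening`, `model_selection`, `fit`, `trend`,
#'   `projection`, `forecast`, `impact_pct`, `summary`.
#' @export
run_pipeline <- function(strandings = NULL, sst = NULL, hatchlings = NULL,
                         nao = NULL, amo = NULL, scenario = NULL,
                         max_open = 150L, min_length = 14L,
                         n_trees = 2000L, collinearity_threshold = 0.7,
                         negligible = 0.2,
                         n_chains = 3L, n_adapt = 500L, n_burn = 1000L,
                         n_iter = 30000L, thin = 5L, strict = TRUE,
                         trend_last_n = 15L, horizon = 15L,
                         forecast_error_sd = 0.5,
                         assume = population_assumptions(),
                         seed = 1L, out_dir = NULL) {
  have_tables <- !is.null(strandings) || !is.null(sst)
  if (!xor(have_tables, !is.null(scenario))) {
    abort("supply either input tables or a scenario, not both")
  }
  if (!is.null(scenario)) {
    scenario$seed <- stage_seed(seed, "simulate")
    bundle <- make_scenario(scenario)
    strandings <- bundle$strandings
    sst <- bundle$sst
    hatchlings <- bundle$hatchlings
  }
  if (is.null(strandings)) stage_fail("data_io", "missing stranding table")
  if (is.null(sst)) stage_fail("data_io", "missing daily SST table")

  windows <- with_stage("window_search",
    search_all_windows(strandings, sst, max_open = max_open,
                       min_length = min_length))
  covtab <- with_stage("covariates",
    build_covariate_table(strandings, sst, hatchlings, nao, amo,
                          window_results = windows))
  screening <- with_stage("importance",
    two_stage_select(covtab, n_trees = n_trees,
                     threshold = collinearity_threshold,
                     seed = stage_seed(seed, "importance")))
  err_spec <- covariate_error_spec(covtab)
  selection <- with_stage("count_model",
    backward_select(covtab, screening$top_two, err_spec,
                    negligible = negligible,
                    seed = stage_seed(seed, "fit"),
                    n_chains = n_chains, n_adapt = n_adapt,
                    n_burn = n_burn, n_iter = n_iter, thin = thin,
                    strict = strict))

  ## forecast from the final model if it kept a single SST covariate;
  ## otherwise from a single-covariate refit on the best SST predictor
  sst_cov <- grep("^sst_", selection$covariates, value = TRUE)
  fc_fit <- selection$fit
  fc_cov <- selection$covariates
  if (!(length(fc_cov) == 1 && length(sst_cov) == 1)) {
    fc_cov <- grep("^sst_", screening$stage2$predictor, value = TRUE)[1]
    if (is.na(fc_cov)) stage_fail("forecast", "no SST covariate available")
    fc_fit <- with_stage("count_model",
      fit_nb_eiv(covtab, fc_cov, err_spec,
                 seed = stage_seed(seed, "fit"),
                 n_chains = n_chains, n_adapt = n_adapt, n_burn = n_burn,
                 n_iter = n_iter, thin = thin, strict = strict))
    fc_cov <- fc_fit$covariates
  }
  series <- tibble::tibble(year = covtab$year, value = covtab[[fc_cov]])
  fcast <- with_stage("forecast", {
    trend <- fit_sst_trend(series, last_n = trend_last_n)
    projection <- project_sst(trend, horizon = horizon,
                              error_sd = forecast_error_sd)
    list(trend = trend, projection = projection,
         forecast = predict_counts(fc_fit, projection,
                                   seed = stage_seed(seed, "forecast")))
  })
  final_count <- tail(fcast$forecast$count_mean, 1)
  impact <- population_impact(assume, final_count)

  summary <- list(
    seed = as.integer(seed),
    n_years = nrow(strandings),
    windows = as.data.frame(windows),
    top_two = screening$top_two,
    final_covariates = selection$covariates,
    dic_table = as.data.frame(selection$dic_table),
    overdispersion = overdispersion_stat(selection$fit),
    forecast_covariate = fc_cov,
    trend = fcast$trend[c("slope", "intercept", "anchor_year")],
    forecast = as.data.frame(fcast$forecast),
    final_year_predicted_count = final_count,
    population_impact_pct = impact)

  run <- structure(list(
    windows = windows, covariate_table = covtab, screening = screening,
    model_selection = selection, fit = fc_fit, trend = fcast$trend,
    projection = fcast$projection, forecast = fcast$forecast,
    impact_pct = impact, summary = summary, seed = as.integer(seed)),
    class = "coldstun_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(run$windows, file.path(out_dir, "window_results.csv"))
  write_table_csv(run$covariate_table, file.path(out_dir, "covariates.csv"))
  es <- covariate_error_spec(run$covariate_table)
  write_table_csv(
    tibble::tibble(column = es$column, error_type = es$kind,
                   sds = purrr::map_chr(es$sds, paste, collapse = ";")),
    file.path(out_dir, "covariate_error_spec.csv"))
  write_table_csv(run$screening$stage1, file.path(out_dir, "importance_stage1.csv"))
  write_table_csv(run$screening$stage2, file.path(out_dir, "importance_stage2.csv"))
  write_table_csv(run$model_selection$dic_table,
                  file.path(out_dir, "model_comparison.csv"))
  write_table_csv(tidy(run$model_selection$fit),
                  file.path(out_dir, "posterior_summary.csv"))
  write_table_csv(run$forecast, file.path(out_dir, "forecast.csv"))
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "coldstun_stage_error")) stop(e)
    stage_fail(stage, conditionMessage(e))
  })
}

stage_fail <- function(stage, msg) {
  abort(paste0("pipeline stage '", stage, "' failed: ", msg),
        class = "coldstun_stage_error")
}

#' @export
print.coldstun_run <- function(x, ...) {
  cat("Cold-stun analysis run (seed", x$seed, ")\n")
  cat("  top two predictors:", paste(x$screening$top_two, collapse = ", "), "\n")
  cat("  final model:",
      if (length(x$model_selection$covariates))
        paste(x$model_selection$covariates, collapse = " + ")
      else "intercept only", "\n")
  cat(sprintf("  overdispersion: %.3f\n",
              overdispersion_stat(x$model_selection$fit)))
  cat(sprintf("  final-year predictive mean count: %.1f\n",
              x$summary$final_year_predicted_count))
  cat(sprintf("  juvenile population impact: %.2f%%\n", x$impact_pct))
  invisible(x)
}
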
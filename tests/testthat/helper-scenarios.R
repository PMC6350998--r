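# Shared fixture builders. Everything is generated in code; no binary data.

# A tiny daily SST tibble with explicit values starting at `start`.
small_sst <- function(values, start = "2000-01-01", err_sd = 0.2) {
  tibble::tibble(date = as.Date(start) + seq_along(values) - 1,
                 sst = values, sst_err_sd = err_sd)
}

# A complete monthly index table over `years` with N(0, sd) values.
monthly_index_table <- function(years, seed = 1, sd = 1) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(year = as.integer(years), month = 1:12)
    grid$value <- rnorm(nrow(grid), 0, sd)
    grid
  })
}

# Write a data frame to a temp CSV and return the path.
tmp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}

# Scenario truth packaged as model-ready data + error spec.
truth_model_data <- function(scenario) {
  list(data = tibble::tibble(year = scenario$truth$year,
                             count = scenario$strandings$count,
                             x = scenario$truth$x_obs,
                             h = scenario$truth$hatch_lag_avg),
       es = list(x = measurement_error("heteroscedastic",
                                       scenario$truth$x_err_sd)))
}

# Reduced-length MCMC settings for replicate studies (diagnostics are still
# recorded; strict gating is off because chains are intentionally short).
short_mcmc <- list(n_chains = 2L, n_adapt = 300L, n_burn = 500L,
                   n_iter = 1500L, thin = 1L, strict = FALSE)

fit_short <- function(data, covariates, es, seed) {
  do.call(fit_nb_eiv, c(list(data = data, covariates = covariates,
                             error_spec = es, seed = seed), short_mcmc))
}
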
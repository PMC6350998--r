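#' Parameters for a synthetic cold-stun scenario
#'
#' Bundles every ground-truth parameter of the synthetic-data generator.
#' Defaults describe a Gulf-of-Maine-like study system: a 35-year daily SST
#' record with a seasonal cycle peaking in early August, a slow linear
#' warming trend, strongly autocorrelated daily noise, per-day measurement
#' SDs centred near 0.19 deg C, a saturating hatchling-release trend, and
#' annual stranding counts drawn from a negative binomial whose log-mean is
#' linear in a windowed SST statistic (and optionally in lag-averaged
#' hatchlings).
#'
#' The planted climate window runs from 76 to 47 days before 31 December,
#' i.e. 16 October through 14 November — late October through early
#' November, on the cooling limb of the seasonal cycle.
#'
#' @param seed Integer master seed for the scenario.
#' @param n_years Number of stranding years (daily SST is generated for
#'   these years; hatchlings start `hatch_lead` years earlier so lagged
#'   averages exist for every stranding year).
#' @param start_year First stranding year.
#' @param sst_mean_annual Annual-mean SST (deg C) in the first year.
#' @param seasonal_amplitude Amplitude (deg C) of the seasonal sinusoid.
#' @param warming_slope Linear warming trend (deg C / year).
#' @param noise_sd Marginal SD (deg C) of the AR(1) daily noise.
#' @param noise_ar1 AR(1) coefficient of the daily noise, in `[0, 1)`.
#' @param err_sd_mean,err_sd_sd Mean and SD (deg C) of the positive-truncated
#'   normal from which per-day measurement SDs are drawn.
#' @param hatch_carrying_capacity,hatch_growth_rate,hatch_noise_sd Logistic
#'   carrying capacity (hatchlings), growth rate (1/year) and lognormal
#'   noise SD of the hatchling trend.
#' @param hatch_lead Years of hatchling record generated before
#'   `start_year` (must be at least 4 for the lag-2/3/4 average).
#' @param beta0,beta1,beta2 True regression coefficients on the log-mean
#'   scale: intercept, windowed-SST slope, hatchling slope (per hatchling;
#'   keep tiny or zero given the ~1e5 scale of the hatchling series).
#' @param nb_size Negative-binomial dispersion k (> 0); variance is
#'   mu + mu^2 / k.
#' @param planted_window Integer `c(open, close)` day offsets before the
#'   31 December reference (open >= close >= 0).
#' @param planted_stat One of `"mean"`, `"max"`, `"min"`, `"sd"`,
#'   `"days_below_10"`, `"days_above_20"`.
#' @return A list of class `"scenario_params"`.
#' @export
scenario_params <- function(seed = 1L,
                            n_years = 35L,
                            start_year = 1982L,
                            sst_mean_annual = 11,
                            seasonal_amplitude = 7.5,
                            warming_slope = 0.03,
                            noise_sd = 0.8,
                            noise_ar1 = 0.7,
                            err_sd_mean = 0.19,
                            err_sd_sd = 0.02,
                            hatch_carrying_capacity = 4e5,
                            hatch_growth_rate = 0.15,
                            hatch_noise_sd = 0.08,
                            hatch_lead = 16L,
                            beta0 = -8,
                            beta1 = 1.2,
                            beta2 = 0,
                            nb_size = 5,
                            planted_window = c(76L, 47L),
                            planted_stat = "min") {
  p <- list(seed = as.integer(seed), n_years = as.integer(n_years),
            start_year = as.integer(start_year),
            sst_mean_annual = sst_mean_annual,
            seasonal_amplitude = seasonal_amplitude,
            warming_slope = warming_slope, noise_sd = noise_sd,
            noise_ar1 = noise_ar1, err_sd_mean = err_sd_mean,
            err_sd_sd = err_sd_sd,
            hatch_carrying_capacity = hatch_carrying_capacity,
            hatch_growth_rate = hatch_growth_rate,
            hatch_noise_sd = hatch_noise_sd,
            hatch_lead = as.integer(hatch_lead),
            beta0 = beta0, beta1 = beta1, beta2 = beta2,
            nb_size = nb_size,
            planted_window = as.integer(planted_window),
            planted_stat = match.arg(planted_stat, aggregate_stats()))
  stopifnot(p$n_years >= 1, p$noise_sd >= 0,
            p$noise_ar1 >= 0, p$noise_ar1 < 1,
            p$err_sd_mean > 0, p$err_sd_sd > 0,
            p$hatch_noise_sd >= 0, p$nb_size > 0, p$hatch_lead >= 4,
            length(p$planted_window) == 2,
            p$planted_window[1] >= p$planted_window[2],
            p$planted_window[2] >= 0)
  structure(p, class = "scenario_params")
}

#' Simulate a daily regional-mean SST series
#'
#' Daily truth = annual mean + warming trend + seasonal sinusoid (annual
#' maximum in early August, day-of-year 217) + stationary AR(1) noise.
#' Per-day measurement SDs are drawn from a positive-truncated normal; they
#' describe how precisely each daily mean is observed and feed the
#' measurement-error model downstream, but are not added to the series
#' itself (the series is the truth the generator plants).
#'
#' @param params A [scenario_params()] object.
#' @return A daily SST tibble (`date`, `sst`, `sst_err_sd`) covering
#'   1 January of `start_year` through 31 December of the last year.
#' @export
simulate_daily_sst <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  withr::with_seed(params$seed, simulate_daily_sst_impl(params))
}

simulate_daily_sst_impl <- function(params) {
  y0 <- params$start_year
  dates <- seq(as.Date(paste0(y0, "-01-01")),
               as.Date(paste0(y0 + params$n_years - 1L, "-12-31")), by = "day")
  yr_frac <- as.numeric(dates - dates[1]) / 365.25
  doy <- as.integer(format(dates, "%j"))
  seasonal <- params$seasonal_amplitude * cos(2 * pi * (doy - 217) / 365.25)
  n <- length(dates)
  if (params$noise_sd > 0) {
    innov_sd <- params$noise_sd * sqrt(1 - params$noise_ar1^2)
    noise <- as.numeric(
      stats::arima.sim(list(ar = params$noise_ar1), n = n, sd = innov_sd))
  } else {
    noise <- numeric(n)
  }
  err_sd <- rtruncnorm_pos(n, params$err_sd_mean, params$err_sd_sd)
  tibble::tibble(
    date = dates,
    sst = params$sst_mean_annual + params$warming_slope * yr_frac +
      seasonal + noise,
    sst_err_sd = err_sd)
}

#' Simulate an annual hatchling-release series
#'
#' Logistic-growth mean (inflection at the midpoint of the lead-in period)
#' multiplied by lognormal noise, rounded to whole hatchlings. The series
#' starts `hatch_lead` years before the first stranding year so that lagged
#' averages exist for every modelled year, and asymptotes towards the
#' carrying capacity in its final decade.
#'
#' @inheritParams simulate_daily_sst
#' @return A tibble with columns `year`, `hatchlings`.
#' @export
simulate_hatchlings <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  withr::with_seed(params$seed + 1L, simulate_hatchlings_impl(params))
}

simulate_hatchlings_impl <- function(params) {
  years <- seq(params$start_year - params$hatch_lead,
               params$start_year + params$n_years - 1L)
  t_mid <- years[1] + 0.6 * (length(years) - 1)
  mu <- params$hatch_carrying_capacity /
    (1 + exp(-params$hatch_growth_rate * (years - t_mid)))
  noise <- if (params$hatch_noise_sd > 0) {
    exp(rnorm(length(years), -params$hatch_noise_sd^2 / 2,
              params$hatch_noise_sd))
  } else rep(1, length(years))
  tibble::tibble(year = as.integer(years),
                 hatchlings = as.integer(round(mu * noise)))
}

#' Simulate annual stranding counts from planted SST and hatchling drivers
#'
#' For each stranding year the planted aggregate statistic is computed over
#' the planted window of the *true* daily SST series; the log-mean is
#' `beta0 + beta1 * x_t + beta2 * h_t` with `h_t` the lag-2/3/4 hatchling
#' average, and the count is drawn from a negative binomial with dispersion
#' `nb_size`. The covariate later presented to the count model is `x_t`
#' plus normal measurement error whose SD is the mean per-day error SD over
#' the window (one value per year — matching how the model consumes error).
#'
#' @param sst A daily SST tibble from [simulate_daily_sst()].
#' @param hatch A hatchling tibble from [simulate_hatchlings()].
#' @inheritParams simulate_daily_sst
#' @return A tibble with columns `year`, `count`, plus attribute `"truth"`:
#'   a tibble of per-year `x_true`, `x_obs`, `x_err_sd`, `hatch_lag_avg`,
#'   `mu`.
#' @export
simulate_counts <- function(sst, hatch, params) {
  stopifnot(inherits(params, "scenario_params"))
  withr::with_seed(params$seed + 2L, simulate_counts_impl(sst, hatch, params))
}

simulate_counts_impl <- function(sst, hatch, params) {
  years <- seq(params$start_year, params$start_year + params$n_years - 1L)
  w <- params$planted_window
  per_year <- purrr::map(years, function(yr) {
    ref <- as.Date(paste0(yr, "-12-31"))
    slice <- window_slice(sst, ref - w[1], ref - w[2])
    list(x = aggregate_stat_value(slice$sst, params$planted_stat),
         err = mean(slice$sst_err_sd))
  })
  x_true <- purrr::map_dbl(per_year, "x")
  x_err <- purrr::map_dbl(per_year, "err")
  h <- purrr::map_dbl(years, ~ hatchlings_lag_avg(hatch, .x))
  mu <- exp(params$beta0 + params$beta1 * x_true + params$beta2 * h)
  counts <- rnbinom(length(years), size = params$nb_size, mu = mu)
  x_obs <- x_true + rnorm(length(years), 0, x_err)
  out <- tibble::tibble(year = as.integer(years), count = as.integer(counts))
  attr(out, "truth") <- tibble::tibble(
    year = as.integer(years), x_true = x_true, x_obs = x_obs,
    x_err_sd = x_err, hatch_lag_avg = h, mu = mu)
  out
}

#' Generate a complete synthetic scenario bundle
#'
#' Runs the three simulators under one seed and returns every table a real
#' analysis would read, together with the ground-truth record needed to
#' score recovery: the planted window, the true windowed covariate, its
#' observed (error-contaminated) version and per-year error SDs, and the
#' true regression coefficients.
#'
#' @inheritParams simulate_daily_sst
#' @return A list of class `"coldstun_scenario"` with elements `sst`,
#'   `hatchlings`, `strandings`, `truth` (per-year tibble), and `params`.
#' @examples
#' sc <- make_scenario(scenario_params(seed = 42))
#' sc$strandings
#' @export
make_scenario <- function(params = scenario_params()) {
  stopifnot(inherits(params, "scenario_params"))
  sst <- simulate_daily_sst(params)
  hatch <- simulate_hatchlings(params)
  strand <- simulate_counts(sst, hatch, params)
  truth <- attr(strand, "truth")
  attr(strand, "truth") <- NULL
  structure(list(sst = sst, hatchlings = hatch, strandings = strand,
                 truth = truth, params = params),
            class = "coldstun_scenario")
}

#' Write a scenario bundle to a directory of CSVs
#'
#' Emits the same CSV formats the readers accept, plus a manifest recording
#' every ground-truth parameter.
#'
#' @param scenario A [make_scenario()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "coldstun_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(scenario$sst, file.path(dir, "daily_sst.csv"))
  write_table_csv(scenario$hatchlings, file.path(dir, "hatchlings.csv"))
  write_table_csv(scenario$strandings, file.path(dir, "strandings.csv"))
  write_table_csv(scenario$truth, file.path(dir, "truth.csv"))
  jsonlite::write_json(unclass(scenario$params),
                       file.path(dir, "scenario_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

## positive-truncated normal via rejection; vectorised, deterministic under seed
rtruncnorm_pos <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}
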
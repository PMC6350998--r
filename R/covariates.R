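#' The six aggregate SST statistics
#'
#' @return Character vector of the recognised statistic names.
#' @export
aggregate_stats <- function() {
  c("mean", "max", "min", "sd", "days_below_10", "days_above_20")
}

#' Aggregate daily SST over a date window
#'
#' Computes one of the six aggregate statistics of daily mean SST — mean,
#' maximum, minimum, sample standard deviation (n-1 denominator), number of
#' days strictly below 10 deg C, or number of days strictly above 20 deg C —
#' over an inclusive date interval. Every day of the window must be present
#' in the series; a missing day is a hard error, never silently imputed.
#'
#' @param sst A daily SST tibble (`date`, `sst`, ...).
#' @param start,end Inclusive window bounds (Date or ISO-8601 string).
#' @param stat One of [aggregate_stats()].
#' @return A single numeric value (deg C, or a day count for the threshold
#'   statistics).
#' @examples
#' sst <- tibble::tibble(date = as.Date("2000-01-01") + 0:3,
#'                       sst = c(9, 10, 11, 12), sst_err_sd = 0.2)
#' aggregate_sst(sst, "2000-01-01", "2000-01-04", "days_below_10")
#' @export
aggregate_sst <- function(sst, start, end, stat) {
  stat <- match.arg(stat, aggregate_stats())
  slice <- window_slice(sst, as.Date(start), as.Date(end))
  aggregate_stat_value(slice$sst, stat)
}

window_slice <- function(sst, start, end) {
  stopifnot(end >= start)
  slice <- sst[sst$date >= start & sst$date <= end, , drop = FALSE]
  n_expected <- as.integer(end - start) + 1L
  if (nrow(slice) != n_expected) {
    abort(paste0("window ", format(start), "..", format(end), " has ",
                 nrow(slice), " of ", n_expected,
                 " days present; refusing to impute"))
  }
  slice
}

aggregate_stat_value <- function(x, stat) {
  switch(stat,
         mean = mean(x),
         max = max(x),
         min = min(x),
         sd = sd(x),
         days_below_10 = sum(x < 10),
         days_above_20 = sum(x > 20))
}

#' Lag-averaged hatchling abundance for one stranding year
#'
#' Mean of the hatchling releases 2, 3 and 4 years before `year` — the age
#' classes juveniles found in the study area are believed to span.
#'
#' @param h A hatchling tibble (`year`, `hatchlings`).
#' @param year Stranding year.
#' @return Numeric mean of the three lagged values.
#' @export
hatchlings_lag_avg <- function(h, year) {
  lags <- year - c(2L, 3L, 4L)
  idx <- match(lags, h$year)
  if (any(is.na(idx))) {
    abort(paste0("hatchling year(s) missing for lag average of ", year, ": ",
                 paste(lags[is.na(idx)], collapse = ", ")))
  }
  mean(h$hatchlings[idx])
}

#' Summer (June-September) sum of a monthly index
#'
#' @param idx A monthly index tibble (`year`, `month`, `value`).
#' @param year Calendar year.
#' @return Sum of the June, July, August and September values of that year.
#' @export
nao_summer_sum <- function(idx, year) {
  rows <- idx[idx$year == year & idx$month %in% 6:9, , drop = FALSE]
  if (nrow(rows) != 4) {
    abort(paste0("need all of months 6-9 of ", year, "; found ", nrow(rows)))
  }
  sum(rows$value)
}

#' Lagged annual mean of a monthly index
#'
#' Mean of the 12 monthly values of `year - lag`.
#'
#' @inheritParams nao_summer_sum
#' @param lag Lag in whole years (0 for the year itself).
#' @return Numeric mean.
#' @export
annual_index_mean <- function(idx, year, lag = 0L) {
  target <- year - lag
  rows <- idx[idx$year == target, , drop = FALSE]
  if (nrow(rows) != 12) {
    abort(paste0("need all 12 months of ", target, "; found ", nrow(rows)))
  }
  mean(rows$value)
}

#' Assemble the per-year candidate predictor table
#'
#' Builds the default 11-column candidate set: the six aggregate SST
#' statistics, each evaluated at its own best window from a window-search
#' result, plus the NAO summer sum, NAO annual mean lagged 2 years, AMO
#' annual mean, AMO lag-average (mean of lags 1-3), and the lag-2/3/4
#' hatchling average. The SST-minimum column carries per-year
#' heteroscedastic error SDs (the mean per-day measurement SD over its
#' window); the hatchling column carries a single homoscedastic SD derived
#' from the last decade of releases (see [derive_homoscedastic_sd()]).
#' Years whose lagged predictors are unavailable are dropped with a
#' warning.
#'
#' @param strandings Stranding tibble (`year`, `count`).
#' @param sst Daily SST tibble.
#' @param hatchlings Hatchling tibble.
#' @param nao,amo Monthly index tibbles, or `NULL` to omit those columns.
#' @param window_results Tibble from [search_all_windows()] (or
#'   [best_window()] rows bound together): columns `stat`, `open`, `close`.
#' @param predictors Character vector naming which of the 11 default
#'   predictors to build. SST columns are named `sst_<stat>`.
#' @param reference Month-day anchor `"12-31"` of the stranding year from
#'   which window offsets count back.
#' @return A tibble `year`, `count`, then one column per predictor, with
#'   attribute `"error_spec"`: a tibble (`column`, `kind`, `sds` list-col)
#'   recording the measurement-error model of each column.
#' @export
build_covariate_table <- function(strandings, sst, hatchlings = NULL,
                                  nao = NULL, amo = NULL,
                                  window_results = NULL,
                                  predictors = default_predictors(
                                    !is.null(hatchlings), !is.null(nao),
                                    !is.null(amo)),
                                  reference = "12-31") {
  years <- strandings$year
  out <- tibble::tibble(year = years, count = strandings$count)
  err_spec <- tibble::tibble(column = character(), kind = character(),
                             sds = list())
  sst_preds <- intersect(predictors, paste0("sst_", aggregate_stats()))
  if (length(sst_preds) > 0 && is.null(window_results)) {
    abort("window_results required for SST predictors")
  }
  for (pred in sst_preds) {
    stat <- sub("^sst_", "", pred)
    wr <- window_results[window_results$stat == stat, , drop = FALSE]
    if (nrow(wr) != 1) abort(paste0("no window result for stat ", stat))
    vals <- purrr::map(years, function(yr) {
      ref <- as.Date(paste0(yr, "-", reference))
      slice <- window_slice(sst, ref - wr$open, ref - wr$close)
      list(x = aggregate_stat_value(slice$sst, stat),
           err = mean(slice$sst_err_sd))
    })
    out[[pred]] <- purrr::map_dbl(vals, "x")
    if (stat == "min") {
      err_spec <- tibble::add_row(err_spec, column = pred,
                                  kind = "heteroscedastic",
                                  sds = list(purrr::map_dbl(vals, "err")))
    } else {
      err_spec <- tibble::add_row(err_spec, column = pred, kind = "none",
                                  sds = list(numeric(0)))
    }
  }
  if ("nao_summer_sum" %in% predictors) {
    out$nao_summer_sum <- purrr::map_dbl(years, ~ nao_summer_sum(nao, .x))
    err_spec <- tibble::add_row(err_spec, column = "nao_summer_sum",
                                kind = "none", sds = list(numeric(0)))
  }
  if ("nao_lag2" %in% predictors) {
    out$nao_lag2 <- purrr::map_dbl(years, ~ annual_index_mean(nao, .x, 2L))
    err_spec <- tibble::add_row(err_spec, column = "nao_lag2",
                                kind = "none", sds = list(numeric(0)))
  }
  if ("amo_annual" %in% predictors) {
    out$amo_annual <- purrr::map_dbl(years, ~ annual_index_mean(amo, .x, 0L))
    err_spec <- tibble::add_row(err_spec, column = "amo_annual",
                                kind = "none", sds = list(numeric(0)))
  }
  if ("amo_lag_avg" %in% predictors) {
    out$amo_lag_avg <- purrr::map_dbl(
      years,
      ~ mean(c(annual_index_mean(amo, .x, 1L), annual_index_mean(amo, .x, 2L),
               annual_index_mean(amo, .x, 3L))))
    err_spec <- tibble::add_row(err_spec, column = "amo_lag_avg",
                                kind = "none", sds = list(numeric(0)))
  }
  if ("hatchlings_lag_avg" %in% predictors) {
    ok <- purrr::map_lgl(years, ~ all((.x - 2:4) %in% hatchlings$year))
    if (!all(ok)) {
      warn(paste0("dropping year(s) without complete hatchling lags: ",
                  paste(years[!ok], collapse = ", ")))
      out <- out[ok, , drop = FALSE]
      years <- years[ok]
      err_spec$sds <- purrr::map(err_spec$sds,
                                 function(s) if (length(s) > 1) s[ok] else s)
    }
    out$hatchlings_lag_avg <- purrr::map_dbl(
      years, ~ hatchlings_lag_avg(hatchlings, .x))
    err_spec <- tibble::add_row(
      err_spec, column = "hatchlings_lag_avg", kind = "homoscedastic",
      sds = list(derive_homoscedastic_sd(hatchlings)))
  }
  attr(out, "error_spec") <- err_spec
  out
}

default_predictors <- function(with_hatch = TRUE, with_nao = TRUE,
                               with_amo = TRUE) {
  c(paste0("sst_", aggregate_stats()),
    if (with_nao) c("nao_summer_sum", "nao_lag2"),
    if (with_amo) c("amo_annual", "amo_lag_avg"),
    if (with_hatch) "hatchlings_lag_avg")
}

#' Measurement-error specification of a covariate table
#'
#' @param x A covariate table from [build_covariate_table()].
#' @return The `error_spec` attribute tibble.
#' @export
covariate_error_spec <- function(x) {
  spec <- attr(x, "error_spec")
  if (is.null(spec)) abort("no error_spec attribute on this table")
  spec
}
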
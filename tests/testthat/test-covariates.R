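test_that("aggregate_sst reproduces hand arithmetic on a 4-day window", {
  sst <- small_sst(c(9, 10, 11, 12))
  w <- list(s = "2000-01-01", e = "2000-01-04")
  expect_equal(aggregate_sst(sst, w$s, w$e, "min"), 9)
  expect_equal(aggregate_sst(sst, w$s, w$e, "max"), 12)
  expect_equal(aggregate_sst(sst, w$s, w$e, "mean"), 10.5)
  expect_equal(aggregate_sst(sst, w$s, w$e, "sd"), sqrt(5 / 3),
               tolerance = 1e-12)  # 1.2910 by hand, n-1 denominator
  expect_equal(aggregate_sst(sst, w$s, w$e, "days_below_10"), 1)  # strict <
  expect_equal(aggregate_sst(sst, w$s, w$e, "days_above_20"), 0)

  const <- small_sst(rep(7, 5))
  expect_equal(aggregate_sst(const, "2000-01-01", "2000-01-05", "sd"), 0)
  expect_equal(aggregate_sst(const, "2000-01-01", "2000-01-05", "min"),
               aggregate_sst(const, "2000-01-01", "2000-01-05", "max"))

  expect_error(aggregate_sst(sst, "2000-01-01", "2000-01-05", "mean"),
               "refusing to impute")
})

test_that("aggregate_sst agrees with brute-force recomputation on random windows", {
  sst <- simulate_daily_sst(scenario_params(seed = 21, n_years = 3))
  withr::with_seed(42, {
    for (i in 1:200) {
      i0 <- sample(nrow(sst) - 40, 1)
      len <- sample(2:40, 1)
      slice <- sst$sst[i0:(i0 + len - 1)]
      start <- sst$date[i0]; end <- sst$date[i0 + len - 1]
      stat <- sample(aggregate_stats(), 1)
      brute <- switch(stat, mean = sum(slice) / len, max = max(slice),
                      min = min(slice),
                      sd = sqrt(sum((slice - mean(slice))^2) / (len - 1)),
                      days_below_10 = sum(slice < 10),
                      days_above_20 = sum(slice > 20))
      expect_equal(aggregate_sst(sst, start, end, stat), brute,
                   tolerance = 1e-10)
    }
  })
  # min <= mean <= max always; shuffled input rows change nothing
  shuffled <- sst[sample(nrow(sst)), ]
  expect_equal(aggregate_sst(shuffled, "1982-03-01", "1982-03-20", "mean"),
               aggregate_sst(sst, "1982-03-01", "1982-03-20", "mean"))
})

test_that("lagged covariate helpers match hand arithmetic and fail on gaps", {
  h <- tibble::tibble(year = 1996:2000,
                      hatchlings = c(900L, 600L, 300L, 7L, 8L))
  expect_equal(hatchlings_lag_avg(h, 2000), 600)   # (300+600+900)/3
  h2 <- tibble::tibble(year = 1996:1998, hatchlings = c(4L, 2L, 1L))
  expect_equal(hatchlings_lag_avg(h2, 2000), 7 / 3)
  expect_error(hatchlings_lag_avg(h2, 2001), "missing")

  idx <- tibble::tibble(year = 2000L, month = 1:12, value = as.numeric(1:12))
  expect_equal(annual_index_mean(idx, 2000, 0), 6.5)
  expect_equal(annual_index_mean(idx, 2002, 2), 6.5)
  expect_error(annual_index_mean(idx, 2002, 1), "12 months")

  nao <- tibble::tibble(year = 2000L, month = 6:9,
                        value = c(0.1, -0.2, 0.3, 0.4))
  expect_equal(nao_summer_sum(nao, 2000), 0.6)
  expect_error(nao_summer_sum(nao[-2, ], 2000), "months 6-9")
})

test_that("the default candidate table has 11 predictors with error specs", {
  sc <- make_scenario(scenario_params(seed = 9, n_years = 8))
  yrs <- (sc$params$start_year - 5):(sc$params$start_year + 8)
  nao <- monthly_index_table(yrs, seed = 1)
  amo <- monthly_index_table(yrs, seed = 2, sd = 0.2)
  wr <- tibble::tibble(stat = aggregate_stats(),
                       open = 76L, close = 47L)
  ct <- build_covariate_table(sc$strandings, sc$sst, sc$hatchlings,
                              nao, amo, wr)
  expect_equal(ncol(ct) - 2, 11)  # year + count + 11 predictors
  spec <- covariate_error_spec(ct)
  expect_equal(nrow(spec), 11)
  expect_equal(spec$kind[spec$column == "sst_min"], "heteroscedastic")
  expect_length(spec$sds[[which(spec$column == "sst_min")]], nrow(ct))
  expect_equal(spec$kind[spec$column == "hatchlings_lag_avg"], "homoscedastic")

  # restricted predictor set
  ct2 <- build_covariate_table(sc$strandings, sc$sst, sc$hatchlings,
                               window_results = wr,
                               predictors = c("sst_min", "hatchlings_lag_avg"))
  expect_equal(setdiff(names(ct2), c("year", "count")),
               c("sst_min", "hatchlings_lag_avg"))

  # years without complete hatchling lags are dropped with a warning
  short_h <- sc$hatchlings[sc$hatchlings$year >= sc$params$start_year - 3, ]
  expect_warning(
    ct3 <- build_covariate_table(sc$strandings, sc$sst, short_h,
                                 window_results = wr,
                                 predictors = c("sst_min", "hatchlings_lag_avg")),
    "dropping")
  expect_lt(nrow(ct3), nrow(ct))
})

test_that("homoscedastic hatchling SD uses the last decade, n-1 denominator", {
  h <- tibble::tibble(year = 1:12,
                      hatchlings = c(9L, 9L, rep(c(0L, 10L), each = 5)))
  expect_equal(derive_homoscedastic_sd(h), sqrt(250 / 9), tolerance = 1e-12)
  expect_equal(round(derive_homoscedastic_sd(h), 2), 5.27)
  expect_error(derive_homoscedastic_sd(h[1:9, ]), "at least 10")
  const <- tibble::tibble(year = 1:10, hatchlings = rep(5L, 10))
  expect_equal(derive_homoscedastic_sd(const), 0)  # fails later at fit time
})
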
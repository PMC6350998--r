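test_that("read_strandings validates, restricts and orders", {
  df <- tibble::tibble(Year = c(2002, 2000, 2001), Count = c(2, 0, 1))
  out <- read_strandings(tmp_csv(df))
  expect_equal(out$year, 2000:2002)
  expect_equal(out$count, 0:2)

  # range restriction keeps only interior rows and demands completeness
  df5 <- tibble::tibble(year = 1999:2004, count = 0:5)
  out <- read_strandings(tmp_csv(df5), year_range = c(2000, 2002))
  expect_equal(nrow(out), 3)
  expect_error(read_strandings(tmp_csv(df5[-3, ]), year_range = c(2000, 2002)),
               "missing year")
  expect_error(read_strandings(tmp_csv(tibble::tibble(year = c(2000, 2000),
                                                      count = c(1, 2)))),
               "duplicated year")
  expect_error(read_strandings(tmp_csv(tibble::tibble(year = 2000:2001,
                                                      count = c(1.5, 2)))),
               "non-integer")
  expect_error(read_strandings(tmp_csv(tibble::tibble(year = 2000:2001,
                                                      count = c(-1, 2)))),
               "non-negative")
})

test_that("read_hatchlings rejects empty and negative tables", {
  df <- tibble::tibble(year = 1966:1970, hatchlings = c(5, 4, 3, 2, 1) * 100L)
  expect_equal(read_hatchlings(tmp_csv(df))$hatchlings, c(500, 400, 300, 200, 100))
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("year,hatchlings", empty)
  expect_error(read_hatchlings(empty), "empty")
  df$hatchlings[2] <- -1L
  expect_error(read_hatchlings(tmp_csv(df)), "non-negative")
})

test_that("read_daily_sst sorts, and rejects duplicates and zero SDs", {
  df <- tibble::tibble(date = as.Date("2000-01-01") + c(2, 0, 1, 3),
                       sst = c(12, 10, 11, 13), sst_err_sd = 0.2)
  out <- read_daily_sst(tmp_csv(df))
  expect_equal(nrow(out), 4)
  expect_equal(out$sst, c(10, 11, 12, 13))  # returned sorted by date
  expect_error(read_daily_sst(tmp_csv(dplyr::mutate(df, date = df$date[1]))),
               "duplicate date")
  expect_error(read_daily_sst(tmp_csv(dplyr::mutate(df, sst_err_sd = 0))),
               "positive")
})

test_that("read_monthly_index validates months and uniqueness", {
  df <- tibble::tibble(year = 2000L, month = 1:12, value = rnorm(12))
  expect_equal(nrow(read_monthly_index(tmp_csv(df))), 12)
  expect_error(read_monthly_index(tmp_csv(dplyr::mutate(df, month = c(13, 2:12)))),
               "month")
  expect_error(read_monthly_index(tmp_csv(df[c(1, 1, 2:12), ])), "duplicate")
})

test_that("write then read round-trips every field", {
  sc <- make_scenario(scenario_params(seed = 3, n_years = 4))
  dir <- withr::local_tempdir()
  write_table_csv(sc$strandings, file.path(dir, "s.csv"))
  write_table_csv(sc$sst, file.path(dir, "sst.csv"))
  expect_equal(read_strandings(file.path(dir, "s.csv")), sc$strandings)
  back <- read_daily_sst(file.path(dir, "sst.csv"))
  expect_equal(back$date, sc$sst$date)
  expect_equal(back$sst, sc$sst$sst, tolerance = 1e-12)
  expect_equal(back$sst_err_sd, sc$sst$sst_err_sd, tolerance = 1e-12)
})

test_that("packaged stranding fixture covers the study period", {
  path <- system.file("extdata", "s1_strandings_synthetic.csv",
                      package = "coldstunr")
  s1 <- read_strandings(path, year_range = c(1982, 2016))
  expect_equal(nrow(s1), 35)
})
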
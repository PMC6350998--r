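# A degenerate "posterior" with constant draws lets predictive behaviour be
# checked against closed forms without an MCMC run.
fake_fit <- function(b0, b1, k, ndraw = 4000, cov = "x") {
  structure(list(covariates = cov,
                 draws = list(beta0 = rep(b0, ndraw),
                              beta = matrix(b1, ndraw, 1,
                                            dimnames = list(NULL, cov)),
                              k = rep(k, ndraw))),
            class = "nb_eiv_fit")
}

test_that("trend fitting matches hand OLS", {
  const <- tibble::tibble(year = 2001:2010, value = 4.2)
  tr <- fit_sst_trend(const, last_n = 5)
  expect_equal(tr$slope, 0, tolerance = 1e-12)
  expect_equal(tr$intercept, 4.2, tolerance = 1e-12)

  lin <- tibble::tibble(year = 1990:2016, value = 0.05 * (1990:2016) + 3)
  expect_equal(fit_sst_trend(lin, 15)$slope, 0.05, tolerance = 1e-10)

  three <- tibble::tibble(year = 2001:2003, value = c(10, 11, 12))
  tr3 <- fit_sst_trend(three, last_n = 3)
  expect_equal(tr3$slope, 1)
  expect_equal(tr3$intercept, 11)       # value at the middle (anchor) year
  expect_equal(tr3$anchor_year, 2002)
  expect_error(fit_sst_trend(three, last_n = 1))
})

test_that("projection extrapolates linearly with a constant error SD", {
  tr <- fit_sst_trend(tibble::tibble(year = 2001:2016,
                                     value = 0.04 * (2001:2016)), 15)
  pr <- project_sst(tr, horizon = 15, error_sd = 0.5)
  expect_equal(nrow(pr), 15)
  expect_equal(pr$year[1], 2017)
  expect_equal(pr$value[15] - pr$value[1], 14 * tr$slope, tolerance = 1e-10)
  expect_true(all(pr$sd == 0.5))
  flat <- project_sst(fit_sst_trend(tibble::tibble(year = 2001:2005,
                                                   value = 7), 5), 4)
  expect_true(all(flat$value == 7))
})

test_that("posterior-predictive counts match closed-form and oracle checks", {
  pr <- tibble::tibble(year = 2017:2021,
                       value = seq(10, 11, length.out = 5), sd = 0.3)
  # degenerate posterior: E[count] = exp(b0 + b1 m + b1^2 s^2 / 2)
  fit <- fake_fit(b0 = log(5), b1 = 0, k = 1e6)
  fc <- predict_counts(fit, pr, seed = 2)
  expect_equal(fc$count_mean, rep(5, 5), tolerance = 0.15)

  fit2 <- fake_fit(b0 = -6, b1 = 1, k = 50, ndraw = 20000)
  fc2 <- predict_counts(fit2, pr, seed = 3)
  closed <- exp(-6 + pr$value + 0.3^2 / 2)
  # NB draw noise: var = m + m^2 (1/k + (e^{s^2 b1^2}-1)(1+1/k)) approx.;
  # generous 3-MCSE style tolerance via the simulated SD itself
  expect_equal(fc2$count_mean, closed, tolerance = 0.05)
  expect_true(all(diff(fc2$count_mean) > 0))   # warming => rising predictions

  # determinism and interval ordering
  expect_identical(predict_counts(fit2, pr, seed = 3), fc2)
  expect_true(all(fc2$count_q025 <= fc2$count_mean))
  expect_true(all(fc2$count_mean <= fc2$count_q975))

  # intervals widen (or stay equal) as the projection error SD grows
  pr_wide <- dplyr::mutate(pr, sd = 1.5)
  fc_wide <- predict_counts(fit2, pr_wide, seed = 3)
  expect_true(all(fc_wide$count_q975 - fc_wide$count_q025 >=
                    fc2$count_q975 - fc2$count_q025))
})

test_that("population impact follows the stated arithmetic", {
  a <- population_assumptions()
  expect_equal(population_impact(a, 0), 0)
  # hand arithmetic: (32060 + 23057 + 22918) / mean(0.65, 0.74) juveniles
  hand_total <- (32060 + 23057 + 22918) / mean(c(0.65, 0.74))
  expect_equal(population_impact(a, 2349), 100 * 2349 / hand_total,
               tolerance = 1e-12)
  expect_equal(round(population_impact(a, 2349), 4), 2.0921)
  expect_equal(population_impact(a, 2 * 2349),
               2 * population_impact(a, 2349), tolerance = 1e-12)
  expect_error(population_assumptions(sex_ratio_insitu = 1.2))
})
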
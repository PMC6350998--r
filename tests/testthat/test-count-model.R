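# Single-seed fits here stay cheap; distributional claims (coverage,
# attenuation, calibration) live in the acceptance suite with many seeds.

test_that("the EIV fit recovers planted coefficients on one scenario", {
  sc <- make_scenario(scenario_params(seed = 7))
  md <- truth_model_data(sc)
  fit <- fit_short(md$data, "x", md$es, seed = 11)
  est <- tidy(fit)
  b1 <- est[est$parameter == "beta_x", ]
  expect_lt(abs(b1$mean - sc$params$beta1), 0.35)
  expect_true(b1$q025 < sc$params$beta1 && sc$params$beta1 < b1$q975)
  expect_true(all(fit$fitted$mu_mean > 0))
  # interval ordering invariant
  expect_true(all(est$q025 <= est$mean & est$mean <= est$q975))
})

test_that("vanishing error SDs reproduce the naive fit", {
  sc <- make_scenario(scenario_params(seed = 8))
  md <- truth_model_data(sc)
  tiny <- list(x = measurement_error("heteroscedastic",
                                     rep(1e-6, nrow(md$data))))
  f_eiv <- fit_short(md$data, "x", tiny, seed = 3)
  f_naive <- fit_short(md$data, "x", NULL, seed = 3)
  b_eiv <- tidy(f_eiv); b_naive <- tidy(f_naive)
  expect_equal(b_eiv$mean[b_eiv$parameter == "beta_x"],
               b_naive$mean[b_naive$parameter == "beta_x"],
               tolerance = 0.05)
})

test_that("fit errors are loud and convergence gating works", {
  sc <- make_scenario(scenario_params(seed = 9))
  md <- truth_model_data(sc)
  d_bad <- dplyr::mutate(md$data, x = 1)
  expect_error(fit_short(d_bad, "x", NULL, seed = 1), "zero-variance")
  # absurdly short chains cannot meet strict convergence bounds
  expect_error(
    fit_nb_eiv(md$data, "x", md$es, n_chains = 2, n_adapt = 100,
               n_burn = 0, n_iter = 60, seed = 1, strict = TRUE),
    class = "coldstunr_convergence_error")
  expect_error(measurement_error("heteroscedastic", c(0.1, 0)), "positive")
})

test_that("DIC, overdispersion and residual ACF follow their definitions", {
  sc <- make_scenario(scenario_params(seed = 10))
  md <- truth_model_data(sc)
  fit <- fit_short(md$data, "x", md$es, seed = 2)
  fit_again <- fit_short(md$data, "x", md$es, seed = 2)
  expect_identical(dic(fit), dic(fit_again))          # same seed, same DIC
  expect_equal(dic(fit), unname(2 * fit$dic_components["d_bar"] -
                                  fit$dic_components["d_hat"]))

  # overdispersion statistic recomputed from the stored residuals
  n <- fit$n; p_fixed <- length(fit$covariates) + 1
  expect_equal(overdispersion_stat(fit),
               sum(fit$pearson^2) / (n - p_fixed), tolerance = 1e-12)

  # ACF: lag 0 is 1; values match a hand-rolled autocorrelation
  a <- residual_acf(fit, max_lag = 6)
  expect_equal(a$acf[1], 1)
  r <- fit$pearson - mean(fit$pearson)
  hand_acf2 <- sum(r[1:(n - 2)] * r[3:n]) / sum(r^2)
  expect_equal(a$acf[a$lag == 2], hand_acf2, tolerance = 1e-10)

  # intercept-only fit loses to the covariate fit on this strong signal
  fit0 <- fit_short(md$data, character(0), NULL, seed = 2)
  expect_lt(dic(fit), dic(fit0))
})

test_that("backward selection drops a null hatchling covariate", {
  sc <- make_scenario(scenario_params(seed = 12, beta2 = 0))
  md <- truth_model_data(sc)
  md$data$h <- md$data$h / 1e5          # keep the scale civil
  es <- c(md$es, list(h = measurement_error("homoscedastic", 0.2)))
  sel <- do.call(backward_select,
                 c(list(data = md$data, covariates = c("x", "h"),
                        error_spec = es, seed = 5), short_mcmc))
  expect_true("x" %in% sel$covariates)
  expect_false("h" %in% sel$covariates)
  expect_true("intercept_only" %in% sel$dic_table$model)
  expect_gte(nrow(sel$dic_table), 3)    # full, reduced, null all recorded
  # the recorded table is sorted best-first
  expect_true(!is.unsorted(sel$dic_table$dic))
})
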
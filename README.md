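# coldstunr

Cold-stunning — hypothermic debilitation after prolonged exposure to cold
water — strands hundreds of juvenile Kemp's ridley sea turtles
(*Lepidochelys kempii*) on Cape Cod Bay beaches each autumn, and the annual
totals have grown sharply over four decades. `coldstunr` is an R package
for analysing such annual stranding counts against oceanic, atmospheric
and demographic drivers, and for forecasting future counts as the Gulf of
Maine keeps warming. It is aimed at quantitative ecologists and stranding
network analysts working with an annual count response and daily climate
covariates.

The pipeline has five stages, each usable on its own:

1. **Climate-window search.** For each of six aggregate SST statistics
   (mean, max, min, SD of daily mean SST, days < 10 °C, days > 20 °C) an
   exhaustive sliding-window search finds the day window, anchored at
   31 December of the stranding year, that best explains the counts. A
   window `(open, close)` covers the days `open … close` days before the
   anchor; candidates are scored by small-sample-corrected AIC of a
   Gaussian working model of `log(y + 1)`, and endpoints are reported as
   half-month labels ("late October thru early November").
2. **Covariate engineering.** The windowed SST statistics plus NAO summer
   sum (Jun–Sep), NAO annual mean lagged 2 years, AMO annual mean, AMO
   lag-1–3 average, and hatchling releases lagged 2/3/4 years and averaged
   — 11 candidates by default, each carrying a measurement-error
   specification (per-year SDs for the SST minimum, a constant SD for
   hatchlings derived from the last decade of releases).
3. **Screening.** Out-of-bag permutation importance ("mean decrease in
   accuracy") from a 2,000-tree random forest, run twice: once on all
   candidates, then on the set with collinear SST variables collapsed to
   each group's best member. The top two predictors go forward.
4. **Count model.** A Bayesian negative-binomial regression with covariate
   measurement error:

   ```
   y_t ~ NegBin(mu_t, k)        Var(y_t) = mu_t + mu_t^2 / k
   log mu_t = beta_0 + sum_j beta_j z_jt
   x_jt ~ Normal(z_jt, s_jt)    s_jt fixed (heteroscedastic or constant)
   z_jt ~ Normal(mu_j, sigma_j^2)   (latent truth, learned hyperpriors)
   ```

   fitted by MCMC (JAGS), with DIC backward selection, a Pearson
   overdispersion statistic, residual autocorrelation diagnostics and
   split-chain convergence gating.
5. **Forecast.** OLS slope/intercept of the SST covariate over its last 15
   years, straight-line projection 15 years ahead with a fixed 0.5 °C
   measurement SD, posterior-predictive count distributions per future
   year, and the predicted count as a percentage of the juvenile
   (age 2–4) population.

A synthetic-data generator (`make_scenario()`) plants a known window,
known regression coefficients and known measurement-error levels, so every
stage is testable end to end with ground truth.

## Worked example

```r
library(coldstunr)

sc <- make_scenario(scenario_params(seed = 42))   # truth: beta1 = 1.2, k = 5,
                                                  # min-SST window 76..47 days
wr <- search_all_windows(sc$strandings, sc$sst, max_open = 150)
wr[wr$stat == "min", c("open", "close", "label")]
#>    open close                            label
#> 1    65    47 late October thru early November

ct  <- build_covariate_table(sc$strandings, sc$sst, sc$hatchlings,
                             window_results = wr)
two_stage_select(ct, n_trees = 2000, seed = 1)
#> Two-stage permutation-importance selection
#>   stage 1 ranking: sst_min > sst_days_below_10 > sst_mean > ...
#>   dropped (collinear): sst_mean, sst_max, sst_days_below_10
#>   stage 2 ranking: sst_min > sst_sd > hatchlings_lag_avg > sst_days_above_20
#>   top two: sst_min, sst_sd

fit <- fit_nb_eiv(ct, "sst_min", covariate_error_spec(ct), seed = 1)
fit
#> Bayesian negative-binomial count model (sst_min)
#>   n = 35 years; DIC = 319.40; overdispersion = 0.944
#>   parameter    scale     mean   q025  q975
#> 1 beta0        original -9.07 -12.2  -6.11
#> 2 beta_sst_min original  1.31   1.01  1.63
#> 3 k            original  4.63   2.13  9.18
```

The recovered window sits on the planted late-October/early-November span;
the slope posterior (1.31, 95% CI 1.01–1.63) covers the planted 1.2 —
warmer late-fall minima mean more cold-stuns; the overdispersion statistic
near 1 says the negative binomial absorbs the extra-Poisson variation.
Forecasting continues from the same fit:

```r
series <- tibble::tibble(year = ct$year, value = ct$sst_min)
proj <- project_sst(fit_sst_trend(series, 15), horizon = 15, error_sd = 0.5)
fc <- predict_counts(fit, proj, seed = 1)
tail(fc, 1)
#>   year sst_projected sst_sd count_mean count_q025 count_q975
#> 1 2031         10.70    0.5      184.8         21        686
population_impact(population_assumptions(), tail(fc$count_mean, 1))
#> [1] 0.165   # percent of the age-2..4 juvenile population
```

`autoplot(fit)`, `autoplot(fc)`, `plot_importance()` and
`plot_residual_acf()` give the standard diagnostic figures;
`run_pipeline()` chains all five stages from one seed and can write every
stage table plus a `summary.json` to a run directory.

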
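---
title: "Methods: climate windows, errors-in-variables count models, and cold-stun forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate windows, errors-in-variables count models, and cold-stun forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`coldstunr` models annual counts of cold-stunned sea turtles as a function
of windowed sea-surface-temperature (SST) covariates observed with error,
and projects those counts under continued warming. This vignette explains
the statistical machinery, the choices we made where the design was
genuinely open, and what the synthetic-data tests do and do not establish.

## The response and the candidate drivers

The response is one non-negative integer per stranding season: the number
of cold-stunned Kemp's ridleys found between October and January, labelled
by the calendar year the season starts. Counts at this scale are strongly
overdispersed (a handful of extreme years against a low baseline), which
motivates a negative-binomial likelihood with dispersion `k`
(`Var = mu + mu^2/k`) rather than a Poisson.

Candidate drivers fall into three groups:

* **Windowed SST statistics.** Six per-window summaries of daily regional
  mean SST: mean, maximum, minimum, sample SD, days strictly below 10 °C
  (the cold-stun onset temperature), days strictly above 20 °C
  (anomalous warmth). "Below"/"above" are read literally as strict
  inequalities, and the SD uses the n−1 denominator.
* **Climate indices.** The NAO summed over June–September (summer
  recruitment period), the NAO annual mean lagged two years (a Gulf
  Stream position proxy), the AMO annual mean, and the mean of the AMO
  lagged 1–3 years. The plausible candidate enumeration is ambiguous by
  one or two columns; we collapse the three AMO lags into a single
  averaged column so the default candidate set has exactly 11 predictors.
  The set is fully configurable.
* **Hatchling releases** lagged 2, 3 and 4 years and averaged — the age
  classes of the juveniles that strand.

## Climate-window search

A window is a pair of day offsets `(open, close)` counted back from an
anchor at 31 December of the stranding year; it spans
`open − close + 1` days. The search is exhaustive over
`max_open ≥ open ≥ close ≥ 0` with a minimum length, scored per window by
the AICc of a Gaussian linear model of `log(count + 1)` on the windowed
statistic. Defaults: `max_open = 365` days (a full year), minimum length
14 days (half-month resolution, matching how endpoints are reported).

The log1p-Gaussian working model is a deliberate simplification: inside
the search we only need a fast, monotone-in-fit ranking of tens of
thousands of candidate windows, not calibrated inference. The final
inference is always the negative-binomial model. AICc rather than AIC
because the number of years is small (n ≈ 35, three parameters). Exact
ties — common when two windows share their informative days — are broken
in favour of the shorter window, then the window closing nearer the
anchor: the most parsimonious, most recent description of the same
signal. A perfect fit would send `log(RSS)` to −∞, so RSS is floored at
1e−12. Windows with any missing daily value are a hard error; silently
imputing days inside a window would bias minima and threshold counts.

The implementation sweeps all windows with incremental accumulators
(running min/max/sum/sum-of-squares/threshold counts), so the full
365-day triangle costs seconds; tests verify the sweep against a naive
per-window recomputation.

## Permutation-importance screening

"Mean decrease in accuracy" is operationalised the standard way: the
increase in out-of-bag squared prediction error when one predictor's
values are permuted, averaged over the trees of a random-forest
regression (2,000 trees; bootstrap size n; ⌈p/3⌉ candidates per split).
We do not literally refit with the variable removed. Screening is
two-stage: rank all candidates; among SST statistics whose pairwise
absolute correlation reaches 0.7 (connected components of that graph),
keep only the highest-ranked member; re-rank the reduced set and take the
top two forward. The 0.7 cutoff is a convention, not an estimate, and is
configurable. Non-SST candidates are never removed by the screen — the
collinearity problem the screen addresses is specifically the six SST
summaries measuring overlapping windows of the same series.

## The errors-in-variables negative-binomial model

For covariates `j = 1..p` with observed values `x_jt` and known
measurement SDs `s_jt`:

```
y_t   ~ NegBin(mu_t, k)
log mu_t = beta_0 + sum_j beta_j z_jt
x_jt  ~ Normal(z_jt, s_jt^2)
z_jt  ~ Normal(mu_j, sigma_j^2)
```

The SST minimum carries heteroscedastic per-year SDs (the mean of the
per-day observation SDs inside its window, about 0.19 °C); the hatchling
covariate carries one constant SD, the sample SD of the final ten years
of releases — the trend asymptotes there, so its residual year-to-year
wiggle is read as the measurement noise of the whole series. A constant
series would give SD 0, which the fit rejects (error SDs must be
positive). "Scaling observations by" that SD admits two readings; we use
it as the constant measurement-error SD, the reading under which the
error model is well defined.

**Priors.** Covariates are standardised internally (results are
back-transformed, so both scales are reported exactly).
Coefficients get Normal(0, 10²) priors on the standardised scale; the
dispersion gets Gamma(2, 0.1) (mean 20, diffuse over the plausible
1–50 range). The latent-truth prior is *structural*:
`z_jt ~ Normal(mu_j, sigma_j^2)` with learned hyperparameters
(`mu_j ~ Normal(0, 10²)`, `sigma_j ~ Uniform(0, 10)`). This choice is
load-bearing. The tempting alternative — a fixed, very diffuse latent
prior — looks innocuous but leaves the slope posterior attenuated almost
exactly as a naive no-error fit is: with an essentially flat prior on
each `z_t` separately, the posterior of `z_t` shrinks `x_t` towards
nothing, and no attenuation correction happens (the functional
errors-in-variables problem). Learning the latent population mean and
variance lets the model subtract the known measurement variance from the
observed spread, which is what restores an unbiased slope; our
calibration tests (100 replicates) pass with the structural prior and
fail without it.

**Computation.** The posterior is sampled with JAGS; the negative
binomial is parameterised as a Poisson–Gamma mixture
(`y ~ Pois(mu·rho)`, `rho ~ Gamma(k, k)`) so `k` can be continuous.
Defaults are 3 chains × 30,000 iterations thinned by 5 after 500
adaptation and 1,000 burn-in steps — about 10 s per fit — chosen so that
the convergence gate (split-chain potential scale reduction < 1.01 and
total effective sample size > 400 for `beta_0`, every `beta_j` and `k`)
is met with margin on well-behaved data. With `strict = TRUE` (default)
a failed gate is an error carrying the diagnostics table; replicate
simulation studies use short chains with `strict = FALSE`, and the
diagnostics are still recorded on every fit.

**Model comparison and diagnostics.** DIC is computed from the draws as
`Dbar + pD`, `pD = Dbar − D(posterior means)`, with the deviance
*conditional on the latent covariates* (the common default in
latent-variable software; DIC variants differ, so this is stated
explicitly). Backward selection drops a covariate when its removal
lowers DIC, or when its 95% interval spans zero with a standardised
posterior mean below 0.2 in magnitude — a negligibility bound that
mirrors "not important" decisions made on interval-spanning,
near-zero coefficients. Every candidate model's DIC is recorded,
including the intercept-only baseline. The overdispersion statistic is
`sum(r_t^2)/(n − p)` with Pearson residuals at posterior means; values
near 1 indicate the NB variance is adequate. Residual autocorrelation
uses the standard ACF of those residuals. Temporal-dependence
structures (AR(1), random walks) are deliberately out of scope: an ACF
diagnostic is provided instead.

## Forecasting

The SST covariate's trend is an OLS fit to its last 15 years, reported
as a slope and an intercept anchored at the mean fitting year (the OLS
line passes through the mean point, making the two mutually consistent).
Projection is a straight line for 15 further years; each projected value
carries a fixed 0.5 °C measurement SD — deliberately larger than the
observational ~0.19 °C, acknowledging extrapolation uncertainty without
invoking climate-model ensembles. Forecasts are *posterior-predictive*:
per posterior draw, perturb the projected SST by its SD, form
`mu = exp(beta_0 + beta_1 · sst)`, draw a new NB count. Mean-level
intervals would be far too narrow for count data; predictive intervals
carry the count-level noise. The population-impact figure divides the
summed female abundances at ages 2–4 by the averaged female sex ratio to
estimate total juveniles, then expresses the predicted count as a
percentage. With the published abundances (32,060; 23,057; 22,918),
ratios (0.65, 0.74) and a count of 2,349, the arithmetic gives 2.09%;
we implement the stated procedure and report what it computes.

## The synthetic-data generator

`make_scenario()` emulates the study system with known truth: daily SST
as annual mean (11 °C) + linear warming (0.03 °C/yr) + seasonal sinusoid
(amplitude 7.5 °C, maximum in early August, so the late-October window
sits on the cooling limb) + stationary AR(1) noise (marginal SD 0.8 °C,
lag-1 correlation 0.7 — daily SSTs are strongly autocorrelated, and
window minima are sensitive to that); per-day observation SDs from a
positive-truncated Normal(0.19, 0.02²) °C; hatchlings from a logistic
trend with lognormal noise, asymptoting in its final decade; counts from
the NB model with a planted window (days 76..47 before 31 December,
i.e. 16 October–14 November), planted statistic, and planted
coefficients (defaults `beta_0 = −8`, `beta_1 = 1.2` per °C,
`beta_2 = 0`, `k = 5`). Measurement error is applied to the *windowed*
statistic — one value per year, SD equal to the window mean of the
per-day SDs — matching how the count model consumes error.

What the generator does **not** emulate: spatial SST structure, hurricane
forcing, observer-effort changes, and any nonlinearity or interaction in
the count process. Passing tests therefore demonstrate that the
machinery recovers truth *under the model's own assumptions*; they do
not validate those assumptions for real stranding data.

Simulation studies in the test suite use sizes chosen to give stable
verdicts at interactive cost: 50 seeds for window recovery (planted mean
statistic with a strong slope, `beta_0 = −16`, `beta_1 = 2`, searched to
120 days before the anchor), 50 seeds for importance ranking (planted
minimum-SST driver, 2,000 trees), 100 reduced-length MCMC replicates for
coverage/bias/rank-uniformity, 50 seeds for the attenuation comparison
(per-day error SD raised to 0.75 °C so error rivals the covariate
spread), and a fixed scenario for the forecast-versus-brute-force oracle.

## Known limitations

* The window search's working likelihood is Gaussian on `log(y+1)`; for
  weak signals its selected window can differ from an NB-likelihood
  search. It is configurable in principle and exhaustive either way.
* DIC with latent variables is conventional, not canonical; comparisons
  are only meaningful within one conditioning convention.
* The forecast extrapolates a 15-year linear SST trend; it inherits all
  the fragility of straight-line extrapolation and fixed error SDs.
* The impact percentage treats the population snapshot as static over
  the forecast horizon.
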
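#' Linear warming trend of a yearly SST covariate
#'
#' Ordinary least squares on the last `last_n` observations, reported as a
#' slope (deg C / year) and an intercept anchored at the mean year of the
#' fitting span — the OLS line necessarily passes through the mean point of
#' those years, which keeps slope and intercept mutually consistent.
#'
#' @param x A tibble with columns `year` and `value` (the yearly windowed
#'   SST covariate, e.g. the minimum of daily mean SSTs).
#' @param last_n Number of trailing years to fit (default 15).
#' @return A list of class `"sst_trend"`: `slope`, `intercept` (value at
#'   `anchor_year`), `anchor_year` (mean fitting year), `window_n`.
#' @export
fit_sst_trend <- function(x, last_n = 15L) {
  stopifnot(last_n >= 2, nrow(x) >= last_n)
  xx <- tail(dplyr::arrange(x, .data$year), last_n)
  anchor <- mean(xx$year)
  fit <- lm(value ~ I(year - anchor), data = xx)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 anchor_year = anchor, window_n = last_n,
                 last_year = max(xx$year)),
            class = "sst_trend")
}

#' Project the SST covariate forward along the fitted trend
#'
#' Straight-line extrapolation for `horizon` years after the last observed
#' year; every projected value is assigned the same measurement-error SD
#' (default 0.5 deg C) to acknowledge that extrapolated temperatures are
#' more uncertain than observed ones.
#'
#' @param trend An [fit_sst_trend()] object.
#' @param horizon Number of future years.
#' @param error_sd Measurement SD attached to every projected value.
#' @return A tibble (`year`, `value`, `sd`).
#' @export
project_sst <- function(trend, horizon = 15L, error_sd = 0.5) {
  stopifnot(inherits(trend, "sst_trend"), horizon >= 1, error_sd >= 0)
  years <- seq(trend$last_year + 1L, trend$last_year + horizon)
  tibble::tibble(year = as.integer(years),
                 value = trend$intercept +
                   trend$slope * (years - trend$anchor_year),
                 sd = error_sd)
}

#' Posterior-predictive stranding counts for projected SSTs
#'
#' For each posterior draw and future year, the projected SST is perturbed
#' by its measurement SD, the mean `mu = exp(beta0 + beta1 * sst)` is
#' formed from that draw's original-scale coefficients, and a new
#' negative-binomial count is drawn — count-level (not mean-level)
#' uncertainty. The fit must have exactly one covariate (the SST one used
#' in projection).
#'
#' @param fit An `nb_eiv_fit` with a single covariate.
#' @param projected A tibble (`year`, `value`, `sd`) from [project_sst()].
#' @param seed Integer seed for the predictive draws.
#' @return A tibble of class `"coldstun_forecast"`: per year
#'   `sst_projected`, `sst_sd`, `count_mean`, `count_q025`, `count_q975`.
#' @export
predict_counts <- function(fit, projected, seed = 1L) {
  stopifnot(inherits(fit, "nb_eiv_fit"))
  if (length(fit$covariates) != 1) {
    abort("predict_counts needs a single-covariate fit")
  }
  b0 <- fit$draws$beta0
  b1 <- fit$draws$beta[, 1]
  k <- fit$draws$k
  ndraw <- length(b0)
  out <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(projected)), function(i) {
      x_star <- projected$value[i] + rnorm(ndraw, 0, projected$sd[i])
      mu <- exp(b0 + b1 * x_star)
      ys <- rnbinom(ndraw, size = k, mu = mu)
      tibble::tibble(year = projected$year[i],
                     sst_projected = projected$value[i],
                     sst_sd = projected$sd[i],
                     count_mean = mean(ys),
                     count_q025 = quantile(ys, 0.025, names = FALSE),
                     count_q975 = quantile(ys, 0.975, names = FALSE))
    })
  })
  class(out) <- c("coldstun_forecast", class(out))
  out
}

#' Population assumptions for the impact calculation
#'
#' Female abundance at ages two, three and four, and female sex ratios for
#' in-situ and protected nests; defaults are the published 2012 Kemp's
#' ridley estimates (32,060 / 23,057 / 22,918 females; ratios 0.65 and
#' 0.74).
#'
#' @param female_age2,female_age3,female_age4 Female abundances (> 0).
#' @param sex_ratio_insitu,sex_ratio_protected Female sex ratios in (0, 1).
#' @return A list of class `"population_assumptions"`.
#' @export
population_assumptions <- function(female_age2 = 32060,
                                   female_age3 = 23057,
                                   female_age4 = 22918,
                                   sex_ratio_insitu = 0.65,
                                   sex_ratio_protected = 0.74) {
  stopifnot(female_age2 > 0, female_age3 > 0, female_age4 > 0,
            sex_ratio_insitu > 0, sex_ratio_insitu < 1,
            sex_ratio_protected > 0, sex_ratio_protected < 1)
  structure(list(female_age2 = female_age2, female_age3 = female_age3,
                 female_age4 = female_age4,
                 sex_ratio_insitu = sex_ratio_insitu,
                 sex_ratio_protected = sex_ratio_protected),
            class = "population_assumptions")
}

#' Percentage of the juvenile population affected by a predicted count
#'
#' Total juveniles at ages two to four are estimated by dividing the summed
#' female abundances by the averaged female sex ratio; the impact is the
#' predicted cold-stun count as a percentage of that total.
#'
#' @param assume A [population_assumptions()] object.
#' @param predicted_count Predicted annual cold-stun count (>= 0).
#' @return Percentage (0-100 scale).
#' @examples
#' population_impact(population_assumptions(), 2349)  # ~2.09 %
#' @export
population_impact <- function(assume, predicted_count) {
  stopifnot(inherits(assume, "population_assumptions"), predicted_count >= 0)
  females <- assume$female_age2 + assume$female_age3 + assume$female_age4
  ratio <- mean(c(assume$sex_ratio_insitu, assume$sex_ratio_protected))
  total <- females / ratio
  100 * predicted_count / total
}

#' @export
print.sst_trend <- function(x, ...) {
  cat(sprintf(
    "SST trend over last %d years: slope %.4f degC/yr, %.3f degC at %.1f\n",
    x$window_n, x$slope, x$intercept, x$anchor_year))
  invisible(x)
}
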
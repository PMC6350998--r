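#' Plot fitted versus observed counts for a count-model fit
#'
#' Observed annual counts with the posterior mean of `mu_t` and its 95%
#' credible band.
#'
#' @param object An `nb_eiv_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nb_eiv_fit
#' @export
autoplot.nb_eiv_fit <- function(object, ...) {
  df <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mu_q025,
                                      ymax = .data$mu_q975),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mu_mean),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::labs(x = "Year", y = "Cold-stun count",
                  title = "Observed counts and fitted mean (95% credible band)")
}

#' Plot a posterior-predictive forecast
#'
#' Predictive mean and 95% interval of future annual counts.
#'
#' @param object A `coldstun_forecast` tibble from [predict_counts()].
#' @param observed Optional stranding tibble (`year`, `count`) drawn as
#'   points before the forecast horizon.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coldstun_forecast
#' @export
autoplot.coldstun_forecast <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$count_q025,
                                      ymax = .data$count_q975),
                         fill = "firebrick", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$count_mean),
                       colour = "firebrick") +
    ggplot2::labs(x = "Year", y = "Cold-stun count",
                  title = "Posterior-predictive forecast (95% interval)")
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_point(data = observed,
                                 ggplot2::aes(y = .data$count))
  }
  p
}

#' Plot permutation importance rankings
#'
#' @param object An importance tibble from [fit_importance()] or a
#'   `stage_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_importance <- function(object, ...) {
  df <- if (inherits(object, "stage_selection")) object$stage2 else object
  df$predictor <- stats::reorder(df$predictor, df$importance)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance,
                                   y = .data$predictor)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "Mean decrease in accuracy (OOB permutation)",
                  y = NULL, title = "Predictor importance")
}

#' Plot residual autocorrelation of a fit
#'
#' Bars per lag with approximate white-noise bounds at `+/- 2 / sqrt(n)`.
#'
#' @param fit An `nb_eiv_fit`.
#' @param max_lag Largest lag shown.
#' @return A ggplot.
#' @export
plot_residual_acf <- function(fit, max_lag = 10L) {
  df <- residual_acf(fit, max_lag)
  band <- 2 / sqrt(fit$n)
  ggplot2::ggplot(df[df$lag > 0, ],
                  ggplot2::aes(x = .data$lag, y = .data$acf)) +
    ggplot2::geom_col(width = 0.15) +
    ggplot2::geom_hline(yintercept = c(-band, band), linetype = "dashed",
                        colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "Lag (years)", y = "ACF",
                  title = "Pearson-residual autocorrelation")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
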
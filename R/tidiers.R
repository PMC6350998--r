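#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the posterior summary of a count-model fit
#'
#' @param x An `nb_eiv_fit`.
#' @param scale `"original"` (default) or `"standardized"` coefficient
#'   scale; the dispersion `k` is scale-free and always included.
#' @param ... Unused.
#' @return A tibble (`parameter`, `mean`, `q025`, `q975`).
#' @method tidy nb_eiv_fit
#' @export
tidy.nb_eiv_fit <- function(x, scale = c("original", "standardized"), ...) {
  scale <- match.arg(scale)
  out <- x$summary[x$summary$scale %in% c(scale, "original") &
                     (x$summary$scale == scale | x$summary$parameter == "k"), ]
  out <- out[!duplicated(out$parameter), ]
  out[, c("parameter", "mean", "q025", "q975")]
}

#' One-row model summary of a count-model fit
#'
#' @param x An `nb_eiv_fit`.
#' @param ... Unused.
#' @return A tibble with `n`, `n_covariates`, `dic`, `p_d`,
#'   `overdispersion`, `max_rhat`, `min_ess`.
#' @method glance nb_eiv_fit
#' @export
glance.nb_eiv_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_covariates = length(x$covariates),
                 dic = x$dic, p_d = unname(x$dic_components["p_d"]),
                 overdispersion = x$overdispersion,
                 max_rhat = max(x$convergence$rhat),
                 min_ess = min(x$convergence$ess))
}

#' Tidy a two-stage importance selection
#'
#' @param x A `stage_selection`.
#' @param stage Which ranking to return (default the final one).
#' @param ... Unused.
#' @return An importance tibble (`predictor`, `importance`, `rank`).
#' @method tidy stage_selection
#' @export
tidy.stage_selection <- function(x, stage = c("stage2", "stage1"), ...) {
  x[[match.arg(stage)]]
}

#' Tidy a DIC backward selection
#'
#' @param x An `nb_selection`.
#' @param ... Unused.
#' @return The DIC comparison tibble (`model`, `dic`), best first.
#' @method tidy nb_selection
#' @export
tidy.nb_selection <- function(x, ...) x$dic_table

#' @method glance nb_selection
#' @export
glance.nb_selection <- function(x, ...) {
  tibble::tibble(final_model = if (length(x$covariates))
    paste(x$covariates, collapse = " + ") else "intercept_only",
    dic = dic(x$fit), overdispersion = overdispersion_stat(x$fit))
}
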
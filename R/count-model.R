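#' Measurement-error specification for one covariate
#'
#' @param kind `"heteroscedastic"` (one SD per observation),
#'   `"homoscedastic"` (one constant SD) or `"none"`.
#' @param sds Numeric SDs: length n for heteroscedastic, length 1 for
#'   homoscedastic, ignored for none. All SDs must be strictly positive.
#' @return A list of class `"measurement_error"`.
#' @export
measurement_error <- function(kind = c("none", "heteroscedastic",
                                       "homoscedastic"),
                              sds = numeric(0)) {
  kind <- match.arg(kind)
  if (kind != "none" && (length(sds) == 0 || any(sds <= 0))) {
    abort("measurement-error SDs must be strictly positive")
  }
  structure(list(kind = kind, sds = as.numeric(sds)),
            class = "measurement_error")
}

#' Constant measurement SD for the hatchling covariate
#'
#' The hatchling trend asymptotes over its final decade, so the
#' observation-to-observation variation there is read as measurement
#' error for the whole series: the sample SD (n-1 denominator) of the last
#' 10 annual values.
#'
#' @param h Hatchling tibble (`year`, `hatchlings`), at least 10 rows.
#' @return A single numeric SD (downstream fitting requires it to be > 0).
#' @export
derive_homoscedastic_sd <- function(h) {
  if (nrow(h) < 10) abort("need at least 10 years of hatchling data")
  sd(tail(h[order(h$year), ]$hatchlings, 10))
}

#' Fit the Bayesian negative-binomial count model with covariate error
#'
#' Models annual stranding counts as
#' `y_t ~ NegBin(mu_t, k)` with `log mu_t = beta0 + sum_j beta_j z_jt`,
#' where each covariate with a measurement-error spec is treated as a
#' latent true value `z_jt` observed through
#' `x_jt ~ Normal(z_jt, s_jt)` with `s_jt` fixed from the spec
#' (heteroscedastic: per-year SDs; homoscedastic: one SD). Covariates are
#' standardised internally (coefficients are reported on both scales);
#' priors are Normal(0, `prior_beta_sd`^2) on standardised coefficients and
#' Gamma(`prior_k_shape`, `prior_k_rate`) on the dispersion k. Latent
#' covariate values get a structural prior `z_jt ~ Normal(mu_j, sigma_j^2)`
#' whose mean and SD are learned (Normal(0, 10^2) and Uniform(0, 10)
#' hyperpriors on the standardised scale): with a fixed diffuse latent
#' prior the slope posterior stays attenuated exactly as a naive fit is,
#' whereas the hierarchical prior recovers it. The posterior
#' is sampled by MCMC (Gibbs/slice via JAGS; the negative binomial is
#' parameterised as a Poisson-gamma mixture so k may be continuous).
#'
#' Convergence is assessed by split-chain scale reduction and effective
#' sample size on `beta0`, each `beta_j` and `k`; with `strict = TRUE`
#' (the default) failing either bound is an error carrying the
#' diagnostics table.
#'
#' @param data Data frame with the response and covariate columns, one row
#'   per year (e.g. from [build_covariate_table()]).
#' @param covariates Character vector of covariate column names (may be
#'   empty for an intercept-only model).
#' @param error_spec A tibble (`column`, `kind`, `sds` list-column) as
#'   produced by [build_covariate_table()], a named list of
#'   [measurement_error()] objects, or `NULL` for no measurement error.
#' @param response Response column name.
#' @param prior_beta_sd Prior SD of standardised coefficients.
#' @param prior_k_shape,prior_k_rate Gamma prior on the NB dispersion k.
#' @param n_chains,n_adapt,n_burn,n_iter,thin MCMC settings per chain
#'   (`n_iter` counts iterations; `n_iter / thin` draws are kept).
#' @param seed Integer seed (drives JAGS RNG streams).
#' @param strict Error on failed convergence bounds? (diagnostics are
#'   always recorded on the fit).
#' @param rhat_max,ess_min Convergence bounds: split-chain potential scale
#'   reduction and total effective sample size per reported parameter.
#' @param max_lag Largest lag of the residual autocorrelation diagnostic.
#' @return An object of class `"nb_eiv_fit"`; see [tidy.nb_eiv_fit()],
#'   [glance.nb_eiv_fit()], [dic()], [overdispersion_stat()],
#'   [residual_acf()].
#' @export
fit_nb_eiv <- function(data, covariates, error_spec = NULL,
                       response = "count",
                       prior_beta_sd = 10, prior_k_shape = 2,
                       prior_k_rate = 0.1,
                       n_chains = 3L, n_adapt = 500L, n_burn = 1000L,
                       n_iter = 30000L, thin = 5L, seed = 1L, strict = TRUE,
                       rhat_max = 1.01, ess_min = 400, max_lag = 10L) {
  y <- data[[response]]
  n <- length(y)
  stopifnot(n >= 3, all(y >= 0), all(y == round(y)))
  p <- length(covariates)
  es <- normalise_error_spec(error_spec, covariates, n)

  ## standardise covariates; scale error SDs by the same factor
  X <- matrix(0, n, p, dimnames = list(NULL, covariates))
  x_mean <- numeric(p); x_sd <- numeric(p)
  tau <- vector("list", p)
  for (j in seq_len(p)) {
    x <- as.numeric(data[[covariates[j]]])
    if (anyNA(x)) abort(paste0("missing values in covariate ", covariates[j]))
    x_mean[j] <- mean(x); x_sd[j] <- sd(x)
    if (x_sd[j] == 0) abort(paste0("zero-variance covariate ", covariates[j]))
    X[, j] <- (x - x_mean[j]) / x_sd[j]
    ej <- es[[covariates[j]]]
    if (ej$kind == "heteroscedastic") {
      if (length(ej$sds) != n) abort("heteroscedastic SDs must have length n")
      tau[[j]] <- 1 / (ej$sds / x_sd[j])^2
    } else if (ej$kind == "homoscedastic") {
      if (length(ej$sds) != 1) abort("homoscedastic spec needs a single SD")
      tau[[j]] <- rep(1 / (ej$sds / x_sd[j])^2, n)
    }
  }
  has_err <- !vapply(tau, is.null, logical(1))

  model_txt <- build_jags_model(p, has_err, prior_beta_sd,
                                prior_k_shape, prior_k_rate)
  dat <- list(y = as.integer(y), N = n)
  for (j in seq_len(p)) {
    dat[[paste0("x", j)]] <- X[, j]
    if (has_err[j]) dat[[paste0("tau", j)]] <- tau[[j]]
  }
  inits <- lapply(seq_len(n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((seed * 97L + ch) %% .Machine$integer.max),
         beta0 = log(mean(y) + 0.5), k = 1)
  })
  monitors <- c("beta0", if (p > 0) "beta", "k",
                paste0("z", which(has_err)))
  sam <- suppressWarnings({
    jm <- rjags::jags.model(textConnection(model_txt), data = dat,
                            inits = inits, n.chains = n_chains,
                            n.adapt = n_adapt, quiet = TRUE)
    if (n_burn > 0) update(jm, n_burn, progress.bar = "none")
    rjags::coda.samples(jm, monitors, n.iter = n_iter, thin = thin,
                        progress.bar = "none")
  })

  ## assemble draws
  cn <- colnames(sam[[1]])
  pull <- function(name) {
    if (!name %in% cn) {          # JAGS drops "[1]" on length-1 vectors
      name <- sub("\\[1\\]$", "", name)
    }
    unlist(lapply(sam, function(m) as.numeric(m[, name])))
  }
  beta0_std <- pull("beta0")
  k_draws <- pull("k")
  ndraw <- length(beta0_std)
  beta_std <- if (p > 0) {
    do.call(cbind, lapply(seq_len(p), function(j) pull(paste0("beta[", j, "]"))))
  } else matrix(0, ndraw, 0)
  Z <- array(0, c(ndraw, n, p))
  for (j in seq_len(p)) {
    Z[, , j] <- if (has_err[j]) {
      do.call(cbind, lapply(seq_len(n), function(t)
        as.numeric(pull(paste0("z", j, "[", t, "]")))))
    } else matrix(X[, j], ndraw, n, byrow = TRUE)
  }

  ## fitted mean draws and derived diagnostics
  eta <- matrix(beta0_std, ndraw, n)
  for (j in seq_len(p)) eta <- eta + beta_std[, j] * Z[, , j]
  mu_draws <- exp(eta)
  mu_hat <- colMeans(mu_draws)
  k_hat <- mean(k_draws)

  dev_draws <- vapply(seq_len(ndraw), function(d) {
    -2 * sum(stats::dnbinom(y, size = k_draws[d], mu = mu_draws[d, ], log = TRUE))
  }, numeric(1))
  d_bar <- mean(dev_draws)
  eta_hat <- mean(beta0_std) + if (p > 0) {
    z_bar <- apply(Z, c(2, 3), mean)           # n x p posterior-mean latents
    as.numeric(z_bar %*% colMeans(beta_std))
  } else rep(0, n)
  mu_plug <- exp(eta_hat)
  d_hat <- -2 * sum(stats::dnbinom(y, size = k_hat, mu = mu_plug, log = TRUE))
  p_d <- d_bar - d_hat
  dic_val <- d_bar + p_d

  pearson <- (y - mu_hat) / sqrt(mu_hat + mu_hat^2 / k_hat)
  overdisp <- sum(pearson^2) / (n - (p + 1))
  acf_vals <- as.numeric(acf(pearson, lag.max = max_lag, plot = FALSE)$acf)

  ## original-scale coefficients
  beta_orig <- beta_std
  beta0_orig <- beta0_std
  for (j in seq_len(p)) {
    beta_orig[, j] <- beta_std[, j] / x_sd[j]
    beta0_orig <- beta0_orig - beta_std[, j] * x_mean[j] / x_sd[j]
  }
  if (p > 0) colnames(beta_orig) <- colnames(beta_std) <- covariates

  ## convergence diagnostics on reported parameters
  pull_chains <- function(name) {
    if (!name %in% cn) name <- sub("\\[1\\]$", "", name)
    lapply(sam, function(m) as.numeric(m[, name]))
  }
  par_mats <- c(list(beta0 = pull_chains("beta0"), k = pull_chains("k")),
                if (p > 0) setNames(lapply(seq_len(p), function(j) {
                  pull_chains(paste0("beta[", j, "]"))
                }), paste0("beta_", covariates)))
  conv <- purrr::map_dfr(names(par_mats), function(nm) {
    chains <- par_mats[[nm]]
    tibble::tibble(parameter = nm, rhat = split_rhat(chains),
                   ess = sum(vapply(chains, function(ch)
                     as.numeric(coda::effectiveSize(ch)), numeric(1))))
  })
  if (strict && (any(conv$rhat > rhat_max) || any(conv$ess < ess_min))) {
    abort(paste0("MCMC convergence bounds not met (max split-Rhat = ",
                 signif(max(conv$rhat), 4), ", min ESS = ",
                 signif(min(conv$ess), 4), "); increase n_iter/n_burn",
                 " or set strict = FALSE"),
          class = "coldstunr_convergence_error", diagnostics = conv)
  }

  qs <- function(v) c(mean(v), quantile(v, c(0.025, 0.975), names = FALSE))
  summ <- purrr::map_dfr(seq_len(p + 2), function(i) {
    if (i == 1) {
      rows <- list(c("beta0", "standardized", qs(beta0_std)),
                   c("beta0", "original", qs(beta0_orig)))
    } else if (i <= p + 1) {
      j <- i - 1
      rows <- list(c(paste0("beta_", covariates[j]), "standardized",
                     qs(beta_std[, j])),
                   c(paste0("beta_", covariates[j]), "original",
                     qs(beta_orig[, j])))
    } else {
      rows <- list(c("k", "original", qs(k_draws)))
    }
    purrr::map_dfr(rows, ~ tibble::tibble(
      parameter = .x[1], scale = .x[2], mean = as.numeric(.x[3]),
      q025 = as.numeric(.x[4]), q975 = as.numeric(.x[5])))
  })

  fitted <- tibble::tibble(
    year = if ("year" %in% names(data)) data$year else seq_len(n),
    observed = y, mu_mean = mu_hat,
    mu_q025 = apply(mu_draws, 2, quantile, 0.025),
    mu_q975 = apply(mu_draws, 2, quantile, 0.975))

  structure(list(
    summary = summ, covariates = covariates, error_spec = es,
    draws = list(beta0 = beta0_orig, beta = beta_orig, k = k_draws,
                 beta0_std = beta0_std, beta_std = beta_std),
    fitted = fitted, dic = dic_val,
    dic_components = c(d_bar = d_bar, d_hat = d_hat, p_d = p_d),
    overdispersion = overdisp,
    acf = tibble::tibble(lag = 0:max_lag, acf = acf_vals),
    pearson = pearson, convergence = conv,
    n = n, seed = as.integer(seed),
    settings = list(n_chains = n_chains, n_adapt = n_adapt,
                    n_burn = n_burn, n_iter = n_iter, thin = thin)),
    class = "nb_eiv_fit")
}

#' Deviance information criterion of a fit
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(posterior-mean parameters)`;
#' the deviance is the negative-binomial log likelihood conditional on the
#' latent covariate values (not marginalised over them).
#'
#' @param fit An `nb_eiv_fit`.
#' @return Numeric DIC.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "nb_eiv_fit"))
  fit$dic
}

#' Pearson overdispersion statistic of a fit
#'
#' `sum(r_t^2) / (n - p)` with Pearson residuals
#' `r_t = (y_t - mu_t) / sqrt(mu_t + mu_t^2 / k)` at posterior means and
#' `p` the number of fixed coefficients (intercept included). Values near
#' 1 indicate the negative binomial accounts for the dispersion.
#'
#' @inheritParams dic
#' @return Numeric statistic.
#' @export
overdispersion_stat <- function(fit) {
  stopifnot(inherits(fit, "nb_eiv_fit"))
  fit$overdispersion
}

#' Residual autocorrelation of a fit
#'
#' Autocorrelation function of the Pearson residuals.
#'
#' @inheritParams dic
#' @param max_lag Largest lag.
#' @return A tibble (`lag`, `acf`); lag 0 is always 1.
#' @export
residual_acf <- function(fit, max_lag = 10L) {
  stopifnot(inherits(fit, "nb_eiv_fit"))
  vals <- as.numeric(acf(fit$pearson, lag.max = max_lag, plot = FALSE)$acf)
  tibble::tibble(lag = 0:max_lag, acf = vals)
}

#' Backward model selection by DIC
#'
#' Starting from the full covariate set, repeatedly considers removing
#' each remaining covariate: a covariate is dropped when its removal
#' lowers the DIC, or when its 95% interval spans zero with a standardised
#' posterior mean smaller in magnitude than `negligible`. The search stops
#' when no covariate qualifies. Every candidate model's DIC is recorded,
#' including the intercept-only baseline.
#'
#' @inheritParams fit_nb_eiv
#' @param negligible Magnitude bound (standardised scale) under which a
#'   zero-spanning coefficient is considered ignorable.
#' @param ... Passed on to [fit_nb_eiv()] (priors, sampler settings,
#'   `strict`, ...).
#' @return A list of class `"nb_selection"`: `fit` (final `nb_eiv_fit`),
#'   `covariates` (final set), `dic_table` (tibble `model`, `dic`).
#' @export
backward_select <- function(data, covariates, error_spec = NULL,
                            negligible = 0.2, seed = 1L, ...) {
  model_name <- function(cv) if (length(cv) == 0) "intercept_only"
    else paste(cv, collapse = " + ")
  fits <- list()
  get_fit <- function(cv, s) {
    nm <- model_name(cv)
    if (is.null(fits[[nm]])) {
      fits[[nm]] <<- fit_nb_eiv(data, cv, error_spec, seed = s, ...)
    }
    fits[[nm]]
  }
  current <- covariates
  fit_cur <- get_fit(current, seed)
  repeat {
    if (length(current) == 0) break
    cand <- purrr::map(current, ~ get_fit(setdiff(current, .x), seed + 1L))
    cand_dic <- purrr::map_dbl(cand, dic)
    std <- fit_cur$summary[fit_cur$summary$scale == "standardized" &
                             fit_cur$summary$parameter != "beta0", ]
    spans0 <- purrr::map_lgl(current, function(cv) {
      row <- std[std$parameter == paste0("beta_", cv), ]
      row$q025 < 0 && row$q975 > 0 && abs(row$mean) < negligible
    })
    droppable <- (cand_dic < dic(fit_cur)) | spans0
    if (!any(droppable)) break
    pick <- which(droppable)[which.min(cand_dic[droppable])]
    current <- setdiff(current, current[pick])
    fit_cur <- cand[[pick]]
  }
  if (length(covariates) > 0) get_fit(character(0), seed + 2L)
  dic_table <- tibble::tibble(model = names(fits),
                              dic = purrr::map_dbl(fits, dic))
  structure(list(fit = fit_cur, covariates = current,
                 dic_table = dplyr::arrange(dic_table, .data$dic)),
            class = "nb_selection")
}

#' @export
print.nb_eiv_fit <- function(x, ...) {
  cat("Bayesian negative-binomial count model",
      if (length(x$covariates)) paste0("(", paste(x$covariates, collapse = ", "), ")")
      else "(intercept only)", "\n")
  cat(sprintf("  n = %d years; DIC = %.2f; overdispersion = %.3f\n",
              x$n, x$dic, x$overdispersion))
  print(x$summary[x$summary$scale != "standardized" |
                    x$summary$parameter == "k", ])
  invisible(x)
}

#' @export
print.nb_selection <- function(x, ...) {
  cat("DIC backward selection\n  final covariates:",
      if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(intercept only)", "\n")
  print(x$dic_table)
  invisible(x)
}

## ---- internals ------------------------------------------------------------

normalise_error_spec <- function(error_spec, covariates, n) {
  out <- setNames(vector("list", length(covariates)), covariates)
  for (cv in covariates) out[[cv]] <- measurement_error("none")
  if (is.null(error_spec)) return(out)
  if (is.data.frame(error_spec)) {
    for (i in seq_len(nrow(error_spec))) {
      col <- error_spec$column[i]
      if (!col %in% covariates) next
      kind <- error_spec$kind[i]
      sds <- error_spec$sds[[i]]
      out[[col]] <- if (kind == "none") measurement_error("none")
        else measurement_error(kind, sds)
    }
    return(out)
  }
  for (cv in intersect(names(error_spec), covariates)) {
    e <- error_spec[[cv]]
    stopifnot(inherits(e, "measurement_error"))
    out[[cv]] <- e
  }
  out
}

build_jags_model <- function(p, has_err, prior_beta_sd, k_shape, k_rate) {
  prec <- 1 / prior_beta_sd^2
  terms <- if (p > 0) {
    paste(vapply(seq_len(p), function(j) {
      src <- if (has_err[j]) paste0("z", j, "[t]") else paste0("x", j, "[t]")
      paste0(" + beta[", j, "] * ", src)
    }, character(1)), collapse = "")
  } else ""
  ## structural latent model: z ~ N(mu_z, sigma_z^2) with learned
  ## hyperparameters — a fixed diffuse latent prior leaves the slope
  ## attenuated, the hierarchical prior restores calibration
  err_blocks <- paste(vapply(which(has_err), function(j) {
    paste0("  for (t in 1:N) {\n",
           "    x", j, "[t] ~ dnorm(z", j, "[t], tau", j, "[t])\n",
           "    z", j, "[t] ~ dnorm(muz", j, ", tauz", j, ")\n",
           "  }\n",
           "  muz", j, " ~ dnorm(0, 0.01)\n",
           "  tauz", j, " <- pow(sigz", j, ", -2)\n",
           "  sigz", j, " ~ dunif(0, 10)\n")
  }, character(1)), collapse = "")
  beta_prior <- if (p > 0) {
    paste0("  for (j in 1:", p, ") { beta[j] ~ dnorm(0, ", prec, ") }\n")
  } else ""
  paste0(
    "model {\n",
    "  for (t in 1:N) {\n",
    "    y[t] ~ dpois(lam[t])\n",
    "    lam[t] <- mu[t] * rho[t]\n",
    "    rho[t] ~ dgamma(k, k)\n",
    "    log(mu[t]) <- beta0", terms, "\n",
    "  }\n",
    err_blocks,
    "  beta0 ~ dnorm(0, ", prec, ")\n",
    beta_prior,
    "  k ~ dgamma(", k_shape, ", ", k_rate, ")\n",
    "}\n")
}

## split-chain potential scale reduction (each chain halved)
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(ch) {
    m <- length(ch) %/% 2
    list(ch[seq_len(m)], ch[seq(m + 1, 2 * m)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
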
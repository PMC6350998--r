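#' Enumerate candidate climate windows
#'
#' A window is a pair of day offsets counted back from a reference date:
#' it opens `open` days before the reference and closes `close` days before
#' it (inclusive, so its length is `open - close + 1`).
#'
#' @param max_open Largest opening offset searched (days before reference).
#' @param min_length Smallest admissible window length in days.
#' @return A tibble with integer columns `open`, `close`, one row per
#'   admissible window.
#' @examples
#' enumerate_windows(max_open = 2, min_length = 1)  # 6 windows
#' @export
enumerate_windows <- function(max_open, min_length = 1L) {
  stopifnot(max_open >= 0, min_length >= 1)
  grid <- tidyr::expand_grid(open = 0:max_open, close = 0:max_open)
  dplyr::filter(grid, .data$open >= .data$close,
                .data$open - .data$close + 1L >= min_length)
}

#' Score one climate window against annual stranding counts
#'
#' Computes the chosen aggregate SST statistic over the window for every
#' stranding year (window anchored at the `reference` month-day of that
#' year) and returns the small-sample-corrected AIC of a Gaussian linear
#' model of `log(count + 1)` on that covariate. Lower is better. The
#' log1p-Gaussian working model is a fast, rank-preserving stand-in for a
#' count likelihood during the window search only; the final inference is
#' the negative-binomial model of [fit_nb_eiv()].
#'
#' @param strandings Stranding tibble (`year`, `count`).
#' @param sst Daily SST tibble.
#' @param open,close Window day offsets before the reference (open >= close).
#' @param stat One of [aggregate_stats()].
#' @param reference Month-day anchor, default `"12-31"` of each stranding
#'   year.
#' @return The AICc value (numeric scalar).
#' @export
score_window <- function(strandings, sst, open, close, stat,
                         reference = "12-31") {
  stat <- match.arg(stat, aggregate_stats())
  stopifnot(open >= close, close >= 0)
  x <- purrr::map_dbl(strandings$year, function(yr) {
    ref <- as.Date(paste0(yr, "-", reference))
    aggregate_sst(sst, ref - open, ref - close, stat)
  })
  aicc_simple_lm(log1p(strandings$count), x)
}

#' Find the best climate window for one aggregate statistic
#'
#' Exhaustively minimises [score_window()] over all windows with
#' `max_open >= open >= close >= 0` and length at least `min_length`
#' (or over an explicit `grid`). Ties are broken in favour of the shorter
#' window, then the window closing nearer the reference date.
#'
#' @inheritParams score_window
#' @param max_open,min_length Search-grid bounds (ignored when `grid` is
#'   supplied). The defaults span every window opening up to a year before
#'   the reference with a two-week minimum length.
#' @param grid Optional explicit tibble of `open`, `close` candidates.
#' @return A one-row tibble: `stat`, `open`, `close`, `ic_best`, `ic_null`,
#'   `label` (half-month description such as
#'   `"late October thru early November"`).
#' @export
best_window <- function(strandings, sst, stat, max_open = 365L,
                        min_length = 14L, grid = NULL,
                        reference = "12-31") {
  stat <- match.arg(stat, aggregate_stats())
  yt <- log1p(strandings$count)
  n <- length(yt)
  ic_null <- aicc_null(yt)
  if (!is.null(grid)) {
    scores <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
      score_window(strandings, sst, grid$open[i], grid$close[i], stat,
                   reference)
    })
    best <- pick_best(grid$open, grid$close, scores)
  } else {
    M <- window_day_matrix(strandings$year, sst, max_open, reference)
    best <- sweep_windows(M, yt, stat, max_open, min_length)
  }
  tibble::tibble(stat = stat, open = as.integer(best$open),
                 close = as.integer(best$close), ic_best = best$ic,
                 ic_null = ic_null,
                 label = window_label(best$open, best$close, reference))
}

#' Run the window search for every aggregate statistic
#'
#' @inheritParams best_window
#' @param stats Character vector of statistics to search.
#' @return A tibble with one [best_window()] row per statistic.
#' @export
search_all_windows <- function(strandings, sst, stats = aggregate_stats(),
                               max_open = 365L, min_length = 14L,
                               reference = "12-31") {
  purrr::map_dfr(stats, ~ best_window(strandings, sst, .x, max_open,
                                      min_length, grid = NULL, reference))
}

#' Half-month label for a day of month
#'
#' Days 1-14 are the early half of a month; days after the 14th are the
#' late half.
#'
#' @param day_of_month Integer day 1-31.
#' @return `"early"` or `"late"`.
#' @export
half_month_label <- function(day_of_month) {
  stopifnot(all(day_of_month >= 1), all(day_of_month <= 31))
  ifelse(day_of_month <= 14, "early", "late")
}

#' Half-month description of a window
#'
#' @inheritParams score_window
#' @return Text such as `"late October thru early November"`.
#' @export
window_label <- function(open, close, reference = "12-31") {
  ref <- as.Date(paste0("2001-", reference))  # non-leap exemplar year
  d_open <- ref - open
  d_close <- ref - close
  lab <- function(d) {
    paste(half_month_label(as.integer(format(d, "%d"))),
          month.name[as.integer(format(d, "%m"))])
  }
  paste(lab(d_open), "thru", lab(d_close))
}

## ---- internals ------------------------------------------------------------

## AICc of y ~ x Gaussian linear model, k = 3 params (intercept, slope, sigma)
aicc_simple_lm <- function(y, x) {
  n <- length(y)
  my <- mean(y); syy <- sum((y - my)^2)
  mx <- mean(x); sxx <- sum((x - mx)^2)
  rss <- if (sxx > 0) syy - (sum((x - mx) * (y - my)))^2 / sxx else syy
  aicc_from_rss(rss, n, 3L)
}

aicc_null <- function(y) {
  n <- length(y)
  aicc_from_rss(sum((y - mean(y))^2), n, 2L)
}

aicc_from_rss <- function(rss, n, k) {
  rss <- max(rss, 1e-12)  # guard the perfect-fit limit
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

## matrix of daily SST values: rows = stranding years, column j = value
## (offset j-1) days before that year's reference date; errors on any gap
window_day_matrix <- function(years, sst, max_open, reference) {
  vals <- purrr::map(years, function(yr) {
    ref <- as.Date(paste0(yr, "-", reference))
    dates <- seq(ref - max_open, ref, by = "day")
    idx <- match(dates, sst$date)
    if (anyNA(idx)) {
      abort(paste0("daily SST missing within ", max_open,
                   " days before ", format(ref)))
    }
    rev(sst$sst[idx])  # column 1 = offset 0 (the reference day)
  })
  do.call(rbind, vals)
}

## exhaustive sweep over (open, close) with incremental accumulators;
## scoring is the same closed-form AICc as score_window
sweep_windows <- function(M, yt, stat, max_open, min_length) {
  n <- length(yt)
  my <- mean(yt); syy <- sum((yt - my)^2)
  yc <- yt - my
  best <- list(ic = Inf, open = NA_integer_, close = NA_integer_, len = NA)
  for (close in 0:max_open) {
    acc <- M[, close + 1L]
    r_min <- acc; r_max <- acc; r_sum <- acc; r_sumsq <- acc^2
    r_nb <- as.numeric(acc < 10); r_na <- as.numeric(acc > 20)
    for (open in close:max_open) {
      if (open > close) {
        col <- M[, open + 1L]
        r_min <- pmin(r_min, col); r_max <- pmax(r_max, col)
        r_sum <- r_sum + col; r_sumsq <- r_sumsq + col^2
        r_nb <- r_nb + (col < 10); r_na <- r_na + (col > 20)
      }
      len <- open - close + 1L
      if (len < min_length) next
      x <- switch(stat,
                  mean = r_sum / len,
                  max = r_max,
                  min = r_min,
                  sd = sqrt(pmax(0, (r_sumsq - r_sum^2 / len) / (len - 1))),
                  days_below_10 = r_nb,
                  days_above_20 = r_na)
      mx <- mean(x); sxx <- sum(x^2) - len_scale(n) * mx^2
      rss <- if (sxx > 1e-12) syy - (sum(x * yc))^2 / sxx else syy
      ic <- aicc_from_rss(rss, n, 3L)
      if (ic < best$ic - 1e-9 ||
          (abs(ic - best$ic) <= 1e-9 &&
           (len < best$len || (len == best$len && close < best$close)))) {
        best <- list(ic = ic, open = open, close = close, len = len)
      }
    }
  }
  best
}

len_scale <- function(n) n  # clarity alias: sxx uses the number of years

pick_best <- function(open, close, ic) {
  len <- open - close + 1L
  ord <- order(ic, len, close)
  i <- ord[1]
  list(ic = ic[i], open = open[i], close = close[i], len = len[i])
}
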
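test_that("window enumeration matches brute-force counting", {
  expect_equal(nrow(enumerate_windows(2, 1)), 6)   # all pairs open >= close
  expect_equal(nrow(enumerate_windows(0, 1)), 1)
  expect_equal(nrow(enumerate_windows(3, 5)), 0)   # min_length too large
  # brute force: count admissible pairs directly
  for (mo in c(4, 9)) {
    for (ml in c(1, 3)) {
      brute <- sum(outer(0:mo, 0:mo, function(o, c) o >= c & o - c + 1 >= ml))
      expect_equal(nrow(enumerate_windows(mo, ml)), brute)
    }
  }
})

test_that("half-month labels split months at day 14 and are order-preserving", {
  expect_equal(half_month_label(14), "early")
  expect_equal(half_month_label(15), "late")
  expect_equal(half_month_label(1), "early")
  labs <- half_month_label(1:31)           # total on 1..31
  expect_true(all(labs %in% c("early", "late")))
  expect_true(!is.unsorted(match(labs, c("early", "late"))))
  expect_equal(window_label(76, 47), "late October thru early November")
})

test_that("window scoring matches closed-form AICc behaviour", {
  sc <- make_scenario(scenario_params(seed = 31, n_years = 20))
  y <- sc$strandings
  n <- nrow(y)
  # constant covariate: criterion = null criterion + extra-parameter penalty
  const_sst <- dplyr::mutate(sc$sst, sst = 5)
  s_const <- score_window(y, const_sst, 60, 47, "mean")
  yt <- log1p(y$count)
  rss0 <- sum((yt - mean(yt))^2)
  null_ic <- n * log(rss0 / n) + 4 + 12 / (n - 3)
  expect_equal(s_const, null_ic + 2 + 24 / (n - 4) - 12 / (n - 3),
               tolerance = 1e-8)

  # a covariate exactly collinear with the response crushes the criterion
  lin_sst <- dplyr::mutate(sc$sst,
    sst = log1p(y$count[match(as.integer(format(date, "%Y")), y$year)]))
  s_perfect <- score_window(y, lin_sst, 60, 47, "mean")
  expect_lt(s_perfect, null_ic - 50)

  # determinism
  expect_identical(score_window(y, sc$sst, 60, 47, "min"),
                   score_window(y, sc$sst, 60, 47, "min"))
})

test_that("best_window equals an independent naive minimisation", {
  sc <- make_scenario(scenario_params(seed = 32, n_years = 12))
  grid <- enumerate_windows(25, 5)
  for (stat in c("min", "mean", "sd")) {
    # naive: recompute every covariate with aggregate_sst and lm/AICc by hand
    naive <- vapply(seq_len(nrow(grid)), function(i) {
      x <- vapply(sc$strandings$year, function(yr) {
        ref <- as.Date(paste0(yr, "-12-31"))
        aggregate_sst(sc$sst, ref - grid$open[i], ref - grid$close[i], stat)
      }, numeric(1))
      yt <- log1p(sc$strandings$count)
      f <- lm(yt ~ x)
      rss <- sum(resid(f)^2)
      n <- length(yt); k <- 3
      n * log(max(rss, 1e-12) / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
    }, numeric(1))
    ord <- order(naive, grid$open - grid$close, grid$close)
    best_naive <- grid[ord[1], ]

    bw_sweep <- best_window(sc$strandings, sc$sst, stat, max_open = 25,
                            min_length = 5)
    expect_equal(bw_sweep$open, best_naive$open)
    expect_equal(bw_sweep$close, best_naive$close)
    expect_equal(bw_sweep$ic_best, min(naive), tolerance = 1e-8)

    # explicit-grid path agrees with the sweep
    bw_grid <- best_window(sc$strandings, sc$sst, stat, grid = grid)
    expect_equal(bw_grid[, c("open", "close")], bw_sweep[, c("open", "close")])
  }
})

test_that("adding worse windows or using a singleton grid behaves sanely", {
  sc <- make_scenario(scenario_params(seed = 33, n_years = 12))
  g1 <- enumerate_windows(20, 5)
  b1 <- best_window(sc$strandings, sc$sst, "min", grid = g1)
  # single-window grid returns that window
  single <- best_window(sc$strandings, sc$sst, "min",
                        grid = tibble::tibble(open = 10L, close = 3L))
  expect_equal(c(single$open, single$close), c(10, 3))
  # enlarging the grid with a strictly worse candidate never changes the pick
  s_add <- score_window(sc$strandings, sc$sst, 150, 140, "min")
  expect_gt(s_add, b1$ic_best)            # precondition: it really is worse
  g2 <- dplyr::bind_rows(g1, tibble::tibble(open = 150L, close = 140L))
  b2 <- best_window(sc$strandings, sc$sst, "min", grid = g2)
  expect_equal(b2[, c("open", "close")], b1[, c("open", "close")])
  expect_lte(b1$ic_best, single$ic_best)  # argmin property
})
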
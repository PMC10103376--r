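test_that("normal and exponential ML fits match closed forms and fitdistrplus", {
  y <- c(-1, 0, 1)
  fn <- fit_distribution(y, "normal")
  expect_equal(unname(fn$params["mu"]), 0)
  expect_equal(unname(fn$params["sigma"]), sqrt(2 / 3), tolerance = 1e-12)

  set.seed(21)
  z <- rnorm(500, 5, 2)
  fz <- fit_distribution(z, "normal")
  ora <- fitdistrplus::fitdist(z, "norm")
  expect_equal(unname(fz$params["mu"]), unname(ora$estimate["mean"]),
               tolerance = 1e-6)
  expect_equal(unname(fz$params["sigma"]), unname(ora$estimate["sd"]),
               tolerance = 1e-3)

  e <- rexp(2000, rate = 1 / 0.7)
  fe <- fit_distribution(e, "exponential")
  orae <- fitdistrplus::fitdist(e, "exp")
  expect_equal(unname(fe$params["beta"]), 1 / unname(orae$estimate["rate"]),
               tolerance = 1e-6)
  expect_equal(unname(fe$params["beta"]), 0.7,
               tolerance = 3 * unname(fe$se["beta"]) / 0.7)
  expect_gt(fe$R2, 0.98)
})

test_that("power law with zero shape reduces to the uniform distribution", {
  set.seed(22)
  u <- runif(10000, 2, 5)
  fp <- fit_distribution(u, "powerlaw")
  expect_lt(abs(unname(fp$params["a"])), 3 * unname(fp$se["a"]) + 0.01)
  expect_equal(unname(fp$params["x_max"]), max(u))
  # CDF identity at a = 0: ((x - mu)/(x_max - mu))^1 is the uniform CDF
  fu <- fit_distribution(u, "uniform")
  expect_equal(fp$R2, fu$R2, tolerance = 0.01)
  expect_error(fit_distribution(rep(3, 10), "powerlaw"), "degenerate")
})

test_that("all five families recover generator truth within 3 bootstrap SEs", {
  set.seed(23)
  n <- 10000
  cases <- list(
    list(family = "normal", params = c(mu = 0.33, sigma = 0.09)),
    list(family = "exponential", params = c(beta = 0.7)),
    list(family = "uniform", params = c(min = 1, max = 4)),
    list(family = "triangular", params = c(min = 0, mode = 2, max = 3)),
    list(family = "powerlaw", params = c(mu = 0, x_max = 2, a = -0.34))
  )
  truth_fit <- list(family = NULL, params = NULL)
  class(truth_fit) <- "dist_fit"
  for (case in cases) {
    truth_fit$family <- case$family
    truth_fit$params <- case$params
    y <- simulate_dist(truth_fit, n)
    fit <- fit_distribution(y, case$family)
    bs <- parametric_bootstrap_se(fit, B = 100, seed = 99)
    for (p in names(case$params)) {
      se <- max(bs$se[[p]], 1e-8)
      expect_lt(abs(fit$params[[p]] - case$params[[p]]), 3 * se + 1e-6,
                label = paste(case$family, p))
    }
  }
})

test_that("distribution fitting rejects degenerate inputs and reports modes", {
  expect_error(fit_distribution(c(1, 2), "normal"), "at least 3")
  expect_error(fit_distribution(rep(2, 5), "normal"), "degenerate")
  expect_error(fit_distribution(c(-1, 2, 3), "exponential"), "y >= 0")
  f <- fit_distribution(c(1, 2, 2, 3, 5), "normal")
  expect_equal(f$mode, mean(c(1, 2, 2, 3, 5)))
  fe <- fit_distribution(c(0.1, 0.5, 2, 3), "exponential")
  expect_equal(fe$mode, 0)
})

test_that("spread statistics match direct quantile computation", {
  expect_equal(spread_stat(c(1, 5))$value, 4)
  expect_equal(spread_stat(rep(2, 10))$value, 0)
  y <- 0:1000
  # brute-force oracle: per-tail 0.5% quantile interval
  ora <- unname(quantile(y, 0.995, type = 7) - quantile(y, 0.005, type = 7))
  tr <- spread_stat(y, trim = 0.005)
  expect_equal(tr$value, ora)
  expect_equal(tr$value, 990)
  expect_match(tr$statistic, "trimmed")
  se <- spread_stat(rnorm(200), trim = 0, B = 200, seed = 5)$se
  expect_gt(se, 0)
})

test_that("spread trends over groups follow the constructed pattern", {
  set.seed(24)
  # identical spreads in every group: no trend beats the constant model
  same <- lapply(1:4, function(i) c(0, 5) + i)  # all ranges = 5
  st <- spread_trend(same, family = "quadratic", dist_family = NULL)
  cmp <- compare_models(st$trend, fit_trend(st$group_index, st$spreads,
                                            "constant"))
  expect_lte(cmp$delta_aic, 0)

  # spreads on an exact line
  lin <- lapply(1:4, function(i) c(0, 2 * i))
  stl <- spread_trend(lin, family = "linear", dist_family = NULL)
  expect_equal(stl$trend$R2, 1, tolerance = 1e-10)

  # quadratic pattern of group heterogeneity (high - mid - none - mid)
  widths <- c(32.4, 11.2, 0.5, 17.54)
  grps <- lapply(widths, function(w) runif(8, 0, w))
  stq <- spread_trend(grps, family = "quadratic", dist_family = "uniform",
                      B = 50, seed = 1)
  cmpq <- compare_models(stq$trend,
                         fit_trend(stq$group_index, stq$spreads, "constant"))
  expect_gt(cmpq$er, 1)
  expect_true(all(is.finite(stq$se)))

  expect_warning(spread_trend(list(a = 1:5, b = 2, c = 1:5, d = 1:5),
                              family = "linear", dist_family = NULL),
                 "fewer than 2")
})

test_that("parametric bootstrap SEs track the closed-form rates", {
  set.seed(25)
  y <- rnorm(400, 10, 2)
  fit <- fit_distribution(y, "normal")
  bs <- parametric_bootstrap_se(fit, B = 300, seed = 7)
  expect_equal(unname(bs$se["mu"]),
               unname(fit$params["sigma"]) / sqrt(400), tolerance = 0.15)
  expect_equal(dim(bs$ci), c(2L, 2L))
  # 68% percentile interval spans about +/- 1 SE
  expect_equal(unname(diff(bs$ci[, "mu"])), 2 * unname(bs$se["mu"]),
               tolerance = 0.2)

  e <- rexp(400, 1 / 3)
  fe <- fit_distribution(e, "exponential")
  bse <- parametric_bootstrap_se(fe, B = 300, seed = 8)
  expect_equal(unname(bse$se["beta"]),
               unname(fe$params["beta"]) / sqrt(400), tolerance = 0.15)

  again <- parametric_bootstrap_se(fe, B = 300, seed = 8)
  expect_identical(bse$se, again$se)
})
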
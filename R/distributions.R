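#' Maximum-likelihood fits of the five descriptive distribution families
#'
#' Per-group data are summarized by fitting one of five families and
#' reporting its location (arithmetic mean or mode) and spread. Families
#' and ML estimates:
#' \describe{
#'   \item{normal}{`mu = mean`, `sigma = sqrt(mean((y - mu)^2))` (ML, not
#'     the n-1 estimator); SEs `sigma/sqrt(n)` and `sigma/sqrt(2n)`.}
#'   \item{uniform}{endpoints at the sample extremes (ML).}
#'   \item{exponential}{scale `beta = mean(y)` (equals the mean and the SD);
#'     SE `beta/sqrt(n)`.}
#'   \item{triangular}{support `(a, b)` strictly outside the sample
#'     extremes and mode `c`, by numerical ML (the density vanishes at its
#'     endpoints, so the ML support is strictly wider than the data).}
#'   \item{powerlaw}{the bounded power law with
#'     `CDF = ((x - mu) / (x_max - mu))^(a + 1)`, `x_max > mu`, `a > -1`,
#'     hence `pdf = (a + 1) (x - mu)^a / (x_max - mu)^(a + 1)`.
#'     `x_max` is the sample maximum (the ML boundary value); `mu` is
#'     profiled on a grid below the sample minimum because the likelihood
#'     is unbounded at the boundary; given `mu`, the ML shape is
#'     `a + 1 = 1 / mean(log((x_max - mu) / (y - mu)))`. `a = 0` recovers
#'     the uniform distribution.}
#' }
#'
#' Goodness of fit is reported as an R-squared of the fitted CDF against
#' the empirical CDF (plotting positions `(i - 0.5)/n`) over the sorted
#' data. The mode is reported for families where it is defined.
#'
#' @param y numeric data, `n >= 3`.
#' @param family one of `"normal"`, `"uniform"`, `"triangular"`,
#'   `"exponential"`, `"powerlaw"`.
#' @param mu_grid_size grid resolution for profiling the power-law lower
#'   bound.
#' @return An object of class `dist_fit`: `family`, named `params`, `se`
#'   (ML where available, otherwise via [parametric_bootstrap_se]),
#'   `logLik`, `AIC`, `n`, `R2`, `mode`, and the data.
#' @examples
#' fit_distribution(rnorm(100, 5, 2), "normal")
#' @export
fit_distribution <- function(y, family = c("normal", "uniform", "triangular",
                                           "exponential", "powerlaw"),
                             mu_grid_size = 200L) {
  family <- match.arg(family)
  y <- as.numeric(y)
  stopifnot(all(is.finite(y)))
  n <- length(y)
  if (n < 3L) stop("fit_distribution: need at least 3 observations")
  ymin <- min(y); ymax <- max(y)

  if (family == "normal") {
    mu <- mean(y)
    sigma <- sqrt(mean((y - mu)^2))
    if (sigma == 0) stop("fit_distribution: degenerate (constant) data")
    params <- c(mu = mu, sigma = sigma)
    se <- c(mu = sigma / sqrt(n), sigma = sigma / sqrt(2 * n))
    ll <- sum(stats::dnorm(y, mu, sigma, log = TRUE))
    cdf <- function(x) stats::pnorm(x, mu, sigma)
    mode <- mu
  } else if (family == "uniform") {
    if (ymin == ymax) stop("fit_distribution: degenerate (constant) data")
    params <- c(min = ymin, max = ymax)
    # endpoint MLEs are sample extremes; their sampling error is
    # range/n to first order
    se <- c(min = (ymax - ymin) / n, max = (ymax - ymin) / n)
    ll <- -n * log(ymax - ymin)
    cdf <- function(x) pmin(pmax((x - ymin) / (ymax - ymin), 0), 1)
    mode <- NA_real_
  } else if (family == "exponential") {
    if (any(y < 0)) stop("fit_distribution: exponential requires y >= 0")
    beta <- mean(y)
    if (beta == 0) stop("fit_distribution: degenerate (all-zero) data")
    params <- c(beta = beta)
    se <- c(beta = beta / sqrt(n))
    ll <- sum(stats::dexp(y, rate = 1 / beta, log = TRUE))
    cdf <- function(x) stats::pexp(x, rate = 1 / beta)
    mode <- 0
  } else if (family == "triangular") {
    if (ymin == ymax) stop("fit_distribution: degenerate (constant) data")
    r <- ymax - ymin
    nll <- function(par) {
      a <- ymin - exp(par[1]); b <- ymax + exp(par[2])
      cc <- a + (b - a) * stats::plogis(par[3])
      -sum(log(dtriangular(y, a, cc, b)))
    }
    opt <- stats::optim(c(log(r / 10), log(r / 10), 0), nll,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000))
    a <- ymin - exp(opt$par[1]); b <- ymax + exp(opt$par[2])
    cc <- a + (b - a) * stats::plogis(opt$par[3])
    params <- c(min = a, mode = cc, max = b)
    se <- c(min = NA_real_, mode = NA_real_, max = NA_real_)  # bootstrap
    ll <- -opt$value
    cdf <- function(x) ptriangular(x, a, cc, b)
    mode <- cc
  } else { # powerlaw
    if (ymin == ymax)
      stop("fit_distribution: power law undefined on degenerate support")
    r <- ymax - ymin
    # profile the lower bound on a log-spaced grid below the sample minimum
    offsets <- exp(seq(log(r * 1e-6), log(r), length.out = mu_grid_size))
    prof <- vapply(offsets, function(off) {
      mu <- ymin - off
      m <- mean(log((ymax - mu) / (y - mu)))
      a <- 1 / m - 1
      ll <- n * log(a + 1) + a * sum(log(y - mu)) -
        n * (a + 1) * log(ymax - mu)
      c(mu = mu, a = a, ll = ll)
    }, numeric(3))
    best <- which.max(prof["ll", ])
    mu <- unname(prof["mu", best]); a <- unname(prof["a", best])
    params <- c(mu = mu, x_max = ymax, a = a)
    se <- c(mu = NA_real_, x_max = NA_real_, a = (a + 1) / sqrt(n))
    ll <- prof["ll", best]
    cdf <- function(x) {
      z <- pmin(pmax((x - mu) / (ymax - mu), 0), 1)
      z^(a + 1)
    }
    mode <- if (a > 0) ymax else if (a < 0) mu else NA_real_
  }

  k <- length(params)
  ys <- sort(y)
  e <- (seq_len(n) - 0.5) / n
  Fh <- cdf(ys)
  r2 <- 1 - sum((Fh - e)^2) / sum((e - mean(e))^2)
  structure(
    list(family = family, params = params, se = se, logLik = ll,
         AIC = 2 * k - 2 * ll, n = n, R2 = r2, mode = mode, y = y),
    class = "dist_fit"
  )
}

#' @export
print.dist_fit <- function(x, ...) {
  cat(sprintf("<dist_fit> %s: %s | R2(cdf)=%.4f logLik=%.4g (n=%d)\n",
              x$family,
              paste(sprintf("%s=%.4g", names(x$params), x$params),
                    collapse = " "),
              x$R2, x$logLik, x$n))
  invisible(x)
}

dtriangular <- function(x, a, c, b) {
  d <- numeric(length(x))
  left <- x >= a & x <= c
  right <- x > c & x <= b
  if (c > a) d[left] <- 2 * (x[left] - a) / ((b - a) * (c - a))
  d[right] <- 2 * (b - x[right]) / ((b - a) * (b - c))
  pmax(d, .Machine$double.xmin)
}

ptriangular <- function(x, a, c, b) {
  p <- numeric(length(x))
  left <- x > a & x <= c
  right <- x > c & x < b
  if (c > a) p[left] <- (x[left] - a)^2 / ((b - a) * (c - a))
  p[right] <- 1 - (b - x[right])^2 / ((b - a) * (b - c))
  p[x >= b] <- 1
  p
}

rtriangular <- function(n, a, c, b) {
  u <- stats::runif(n)
  f <- (c - a) / (b - a)
  ifelse(u < f, a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

#' Simulate from a fitted distribution
#'
#' Random draws from a `dist_fit`, used by the parametric bootstrap and by
#' the synthetic-cohort generators.
#'
#' @param fit a `dist_fit`.
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
simulate_dist <- function(fit, n) {
  stopifnot(inherits(fit, "dist_fit"))
  p <- fit$params
  switch(fit$family,
    normal = stats::rnorm(n, p["mu"], p["sigma"]),
    uniform = stats::runif(n, p["min"], p["max"]),
    exponential = stats::rexp(n, rate = 1 / p["beta"]),
    triangular = rtriangular(n, p["min"], p["mode"], p["max"]),
    powerlaw = p["mu"] + (p["x_max"] - p["mu"]) *
      stats::runif(n)^(1 / (p["a"] + 1))
  )
}

#' Range and trimmed-range spread statistics
#'
#' Data spread is summarized as the range (`max - min`) or the 0.5%
#' trimmed range, the distance between the 0.005 and 0.995 empirical
#' quantiles (0.5% trimmed off each tail).
#'
#' @param y numeric data, `n >= 2`.
#' @param trim 0 for the plain range, or a per-tail trimming fraction
#'   (0.005 for the 0.5% trimmed range).
#' @param B nonparametric bootstrap replicates for a standard error
#'   (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `spread_stat`: `statistic`, `value`, `trim`,
#'   `se` (`NA` unless bootstrapped).
#' @export
spread_stat <- function(y, trim = 0, B = 0L, seed = NULL) {
  stopifnot(length(y) >= 2L, trim >= 0, trim < 0.5)
  stat <- function(v) {
    if (trim == 0) max(v) - min(v)
    else diff(stats::quantile(v, c(trim, 1 - trim), names = FALSE, type = 7))
  }
  se <- NA_real_
  if (B > 0L) {
    if (!is.null(seed)) set.seed(seed)
    se <- stats::sd(vapply(seq_len(B),
                           function(i) stat(sample(y, replace = TRUE)),
                           numeric(1)))
  }
  structure(
    list(statistic = if (trim == 0) "range" else
           sprintf("%.1f%% trimmed range", 100 * trim),
         value = unname(stat(y)), trim = trim, se = se),
    class = "spread_stat"
  )
}

#' @export
print.spread_stat <- function(x, ...) {
  cat(sprintf("<spread_stat> %s = %.4g%s\n", x$statistic, x$value,
              if (is.na(x$se)) "" else sprintf(" (SE %.4g)", x$se)))
  invisible(x)
}

#' Trend in per-group spread
#'
#' When the heterogeneity of a response is itself of interest, the
#' per-group spread ([spread_stat]) is modelled for trend over the ordered
#' groups exactly as the means are. Spread standard errors come from a
#' parametric bootstrap of each group's fitted distribution.
#'
#' @param y_by_group named list of numeric vectors, in treatment order.
#' @param family trend family passed to [fit_trend].
#' @param trim passed to [spread_stat].
#' @param dist_family distribution family fitted per group for the
#'   parametric bootstrap of the spread SEs (`NULL` skips the SEs).
#' @param B bootstrap replicates per group.
#' @param seed RNG seed.
#' @return list with `trend` (a `trend_fit` on the spreads), `spreads`,
#'   `se`, and `group_index`.
#' @export
spread_trend <- function(y_by_group, family = "quadratic", trim = 0,
                         dist_family = "normal", B = 200L, seed = NULL) {
  stopifnot(is.list(y_by_group))
  if (!is.null(seed)) set.seed(seed)
  keep <- vapply(y_by_group, function(v) length(v) >= 2L, logical(1))
  if (!all(keep))
    warning("spread_trend: group(s) with fewer than 2 observations ",
            "dropped: ", paste(names(y_by_group)[!keep], collapse = ", "))
  groups <- y_by_group[keep]
  g <- seq_along(y_by_group)[keep] - 1
  spreads <- vapply(groups, function(v) spread_stat(v, trim)$value,
                    numeric(1))
  se <- rep(NA_real_, length(groups))
  if (!is.null(dist_family) && B > 0L) {
    se <- vapply(groups, function(v) {
      fit <- try(fit_distribution(v, dist_family), silent = TRUE)
      if (inherits(fit, "try-error")) return(NA_real_)
      stats::sd(vapply(seq_len(B), function(i)
        spread_stat(simulate_dist(fit, length(v)), trim)$value,
        numeric(1)))
    }, numeric(1))
  }
  list(trend = fit_trend(g, spreads, family), spreads = spreads, se = se,
       group_index = g)
}

#' Parametric bootstrap standard errors and 68% intervals
#'
#' Draws `B` synthetic datasets from a fitted model (`dist_fit` or
#' `trend_fit`), refits each, and reports the standard deviation of the
#' estimates as the SE together with the percentile 68% confidence
#' interval (the "standard error" interval). Replicates whose refit fails
#' are excluded and counted.
#'
#' @param fit a `dist_fit` or `trend_fit`.
#' @param B number of bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @param level percentile interval coverage, default 0.68.
#' @return list with `se` (named), `ci` (2 x p matrix), `failures`, `B`.
#' @export
parametric_bootstrap_se <- function(fit, B = 1000L, seed = NULL,
                                    level = 0.68) {
  stopifnot(B >= 100L)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(fit, "dist_fit")) {
    n <- fit$n
    refit <- function() {
      stats::setNames(
        fit_distribution(simulate_dist(fit, n), fit$family)$params,
        names(fit$params))
    }
  } else if (inherits(fit, "trend_fit")) {
    refit <- function() {
      ysim <- fit$fitted + stats::rnorm(fit$n, 0, fit$sigma)
      fit_trend(fit$group_index, ysim, fit$family)$coefficients
    }
  } else stop("parametric_bootstrap_se: unsupported fit class")
  draws <- vector("list", B)
  failures <- 0L
  for (i in seq_len(B)) {
    est <- try(refit(), silent = TRUE)
    if (inherits(est, "try-error")) failures <- failures + 1L
    else draws[[i]] <- est
  }
  if (failures > 0.1 * B)
    warning("parametric_bootstrap_se: ", failures, " of ", B,
            " refits failed")
  mat <- do.call(rbind, draws[!vapply(draws, is.null, logical(1))])
  alpha <- (1 - level) / 2
  list(se = apply(mat, 2, stats::sd),
       ci = apply(mat, 2, stats::quantile, probs = c(alpha, 1 - alpha)),
       failures = failures, B = B)
}
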
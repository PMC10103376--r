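#' Gaussian trend fits over ordered treatment groups
#'
#' Treatment arms are ordered categories, so group effects are modelled as
#' trends over the ordered group index `g = 0, 1, 2, ...`: a deterministic
#' part from one of four families plus i.i.d. Gaussian noise. Maximum
#' likelihood under Gaussian noise is least squares for the deterministic
#' part; the noise variance is the ML estimate RSS/n. The horizontal line
#' (`constant`) is the null model for model comparison, and with two groups
#' the linear fit reproduces the pooled two-sample t test.
#'
#' Families: `constant` (`y = m`), `linear` (`y = b0 + b1 g`), `quadratic`
#' (`y = b0 + b1 g + b2 g^2`), `exponential` (`y = c exp(k g)`). The
#' exponential is fitted by nonlinear least squares started from a
#' log-linear regression when all `y` share one sign, otherwise from a flat
#' start; a Nelder-Mead polish guards against `nls` failures on degenerate
#' data.
#'
#' @param group_index ordered numeric group indices (treatment intensity).
#' @param y response values.
#' @param family one of `"constant"`, `"linear"`, `"quadratic"`,
#'   `"exponential"`.
#' @return An object of class `trend_fit`: family, coefficients, `sigma`
#'   (ML), `fitted`, `residuals`, `logLik`, `k` (parameter count including
#'   sigma), `n`, `RSS`, `AIC`, `AICc`, `R2`, and the data.
#' @examples
#' g <- rep(0:3, each = 5)
#' y <- 2 - 0.5 * g + rnorm(20, sd = 0.2)
#' fit_trend(g, y, "linear")
#' @export
fit_trend <- function(group_index, y,
                      family = c("constant", "linear", "quadratic",
                                 "exponential")) {
  family <- match.arg(family)
  g <- as.numeric(group_index)
  y <- as.numeric(y)
  stopifnot(length(g) == length(y), all(is.finite(g)), all(is.finite(y)))
  n <- length(y)
  p_det <- switch(family, constant = 1L, linear = 2L, quadratic = 3L,
                  exponential = 2L)
  if (n <= p_det)
    stop("fit_trend: need at least ", p_det + 1L,
         " observations for family '", family, "'")

  if (family == "exponential") {
    fitted_fun <- function(par) par[1] * exp(par[2] * g)
    rss_fun <- function(par) sum((y - fitted_fun(par))^2)
    start <- if (all(y > 0)) {
      cf <- stats::coef(stats::lm(log(y) ~ g))
      c(exp(cf[1]), cf[2])
    } else if (all(y < 0)) {
      cf <- stats::coef(stats::lm(log(-y) ~ g))
      c(-exp(cf[1]), cf[2])
    } else {
      # y spans zero: no log-linear start exists; start flat at the mean
      c(mean(y), 0)
    }
    fit <- try(suppressWarnings(
      stats::nls(y ~ c0 * exp(k * g),
                 start = list(c0 = start[1], k = start[2]),
                 control = stats::nls.control(warnOnly = TRUE))),
      silent = TRUE)
    par <- if (!inherits(fit, "try-error")) stats::coef(fit) else start
    opt <- stats::optim(par, rss_fun, method = "Nelder-Mead")
    if (opt$value < rss_fun(par)) par <- opt$par
    coefs <- c(c0 = unname(par[1]), k = unname(par[2]))
    fv <- fitted_fun(par)
  } else {
    X <- switch(family,
                constant = cbind(`(Intercept)` = rep(1, n)),
                linear = cbind(`(Intercept)` = 1, g = g),
                quadratic = cbind(`(Intercept)` = 1, g = g, g2 = g^2))
    lmf <- stats::lm.fit(X, y)
    coefs <- lmf$coefficients
    fv <- drop(X %*% coefs)
  }
  res <- y - fv
  rss <- sum(res^2)
  sigma <- sqrt(rss / n)
  # floor the ML sigma for the likelihood so perfect fits keep AIC finite
  # and comparable (a perfect null and a perfect alternative then differ
  # by the parameter-count penalty alone)
  sigma_eff <- max(sigma, 1e-10 * (stats::sd(y) + abs(mean(y)) + 1))
  ll <- sum(stats::dnorm(y, fv, sigma_eff, log = TRUE))
  k <- p_det + 1L
  tss <- sum((y - mean(y))^2)
  r2 <- if (family == "constant") 0
        else if (tss > 0) 1 - rss / tss else 0
  aic <- 2 * k - 2 * ll
  aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
  structure(
    list(family = family, coefficients = coefs, sigma = sigma,
         fitted = fv, residuals = res, logLik = ll, k = k, p_det = p_det,
         n = n, RSS = rss, AIC = aic, AICc = aicc, R2 = r2,
         group_index = g, y = y),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s: %s | sigma=%.4g R2=%.4f AIC=%.3f (n=%d)\n",
              x$family,
              paste(sprintf("%s=%.4g", names(x$coefficients),
                            x$coefficients), collapse = " "),
              x$sigma, x$R2, x$AIC, x$n))
  invisible(x)
}

#' Evidence ratio from an AIC difference
#'
#' `ER = exp(dAIC / 2)`, the ratio of Akaike weights of two models whose
#' AICs differ by `dAIC = AIC(null) - AIC(alternative)`. `ER > 1` (and
#' `dAIC > 0`) favors the alternative; `ER < 1` favors the null.
#'
#' @param delta_aic AIC difference(s), null minus alternative.
#' @return evidence ratio(s), same length as `delta_aic`.
#' @examples
#' evidence_ratio(14.65)  # about 1.52e3
#' evidence_ratio(0)      # 1
#' @export
evidence_ratio <- function(delta_aic) exp(delta_aic / 2)

trend_nesting <- list(
  constant = character(0),
  linear = "constant",
  quadratic = c("constant", "linear"),
  exponential = "constant"
)

#' Compare a trend (or nested Gaussian) model against a null
#'
#' Reports the AIC difference `dAIC = AIC(null) - AIC(alt)`, the evidence
#' ratio `exp(dAIC / 2)`, and, when the null is nested in the alternative,
#' the extra-sum-of-squares F test. For two groups and a linear
#' alternative against the constant null the F test is the square of the
#' pooled two-sample t test.
#'
#' @param alt,null `trend_fit` objects fitted to the same data.
#' @param use_aicc use small-sample AICc instead of AIC for the
#'   difference and evidence ratio.
#' @return An object of class `model_comparison`: `delta_aic`, `er`,
#'   `F`, `df`, `p` (the last three `NA` for non-nested pairs).
#' @export
compare_models <- function(alt, null, use_aicc = FALSE) {
  stopifnot(inherits(alt, "trend_fit"), inherits(null, "trend_fit"))
  if (alt$n != null$n || !isTRUE(all.equal(alt$y, null$y)))
    stop("compare_models: models were not fit to identical data")
  daic <- if (use_aicc) null$AICc - alt$AICc else null$AIC - alt$AIC
  er <- evidence_ratio(daic)
  nested <- null$family %in% trend_nesting[[alt$family]]
  if (nested && alt$p_det > null$p_det) {
    df1 <- alt$p_det - null$p_det
    df2 <- alt$n - alt$p_det
    Fstat <- ((null$RSS - alt$RSS) / df1) / (alt$RSS / df2)
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  } else {
    Fstat <- NA_real_; df1 <- NA_integer_; df2 <- NA_integer_; p <- NA_real_
    if (!nested)
      message("compare_models: '", null$family, "' is not nested in '",
              alt$family, "'; F test omitted")
  }
  structure(
    list(delta_aic = daic, er = er, F = Fstat, df = c(df1, df2), p = p,
         alt_family = alt$family, null_family = null$family,
         use_aicc = use_aicc),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s vs %s: dAIC%s=%.4g ER=%.4g%s\n",
              x$alt_family, x$null_family, if (x$use_aicc) "c" else "",
              x$delta_aic, x$er,
              if (is.na(x$p)) ""
              else sprintf(" F(%d,%d)=%.4g p=%.4g", x$df[1], x$df[2],
                           x$F, x$p)))
  invisible(x)
}

#' Welch's t test with an eta-squared effect size
#'
#' Wraps [stats::t.test] (unequal variances, Satterthwaite df) and adds
#' `eta2 = t^2 / (t^2 + df)`. Degenerate inputs (zero variance in both
#' groups) are handled directly: equal means give `t = 0, p = 1`,
#' different means give `p = 0`.
#'
#' @param y1,y2 numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`, `eta2`.
#' @export
welch_t <- function(y1, y2) {
  stopifnot(length(y1) >= 2L, length(y2) >= 2L)
  if (stats::var(y1) == 0 && stats::var(y2) == 0) {
    if (mean(y1) == mean(y2))
      return(list(t = 0, df = NA_real_, p = 1, eta2 = 0))
    return(list(t = Inf * sign(mean(y1) - mean(y2)), df = NA_real_,
                p = 0, eta2 = 1))
  }
  ht <- stats::t.test(y1, y2, var.equal = FALSE)
  t <- unname(ht$statistic)
  df <- unname(ht$parameter)
  list(t = t, df = df, p = ht$p.value, eta2 = t^2 / (t^2 + df))
}

#' Cubic regression spline with a fixed number of interior knots
#'
#' Nonparametric time-course smoother: a cubic B-spline basis with `knots`
#' interior knots (placed at quantiles of `t` unless given), fitted by
#' least squares. Five or six knots resolve the phase structure of the
#' developmental time courses this package targets.
#'
#' @param t time points.
#' @param y values.
#' @param knots number of interior knots (default 6), or pass explicit
#'   `positions`.
#' @param positions optional numeric vector of interior knot positions.
#' @return list with `fitted`, `predict(newt)`, `knots`, `lm`.
#' @export
smoothing_spline <- function(t, y, knots = 6L, positions = NULL) {
  stopifnot(length(t) == length(y))
  n <- length(y)
  if (is.null(positions)) {
    if (n <= knots)
      stop("smoothing_spline: need more observations than knots")
    positions <- stats::quantile(t, probs = seq_len(knots) / (knots + 1),
                                 names = FALSE, type = 7)
  } else if (n <= length(positions)) {
    stop("smoothing_spline: need more observations than knots")
  }
  rng <- range(t)
  basis <- splines::bs(t, knots = positions, degree = 3L,
                       Boundary.knots = rng)
  fit <- stats::lm(y ~ basis)
  beta <- stats::coef(fit)
  beta[is.na(beta)] <- 0
  predict_fun <- function(newt) {
    newt <- pmin(pmax(newt, rng[1]), rng[2])
    nb <- splines::bs(newt, knots = positions, degree = 3L,
                      Boundary.knots = rng)
    drop(cbind(1, nb) %*% beta)
  }
  list(fitted = unname(stats::fitted(fit)), predict = predict_fun,
       knots = positions, lm = fit)
}

#' Correlation of spline-smoothed time courses
#'
#' Smooths two series observed on a common time grid with
#' [smoothing_spline] and returns the Pearson correlation of the fitted
#' curves over a fine grid. Constant series have no defined correlation
#' and return `NA`.
#'
#' @param t common time grid.
#' @param a,b the two series.
#' @param knots interior knots for the smoother.
#' @param grid_n evaluation grid size.
#' @return correlation coefficient, or `NA` for constant series.
#' @export
temporal_correlation <- function(t, a, b, knots = 6L, grid_n = 200L) {
  fa <- smoothing_spline(t, a, knots)
  fb <- smoothing_spline(t, b, knots)
  grid <- seq(min(t), max(t), length.out = grid_n)
  va <- fa$predict(grid)
  vb <- fb$predict(grid)
  tol <- 1e-8
  if (stats::sd(va) <= tol * (abs(mean(va)) + 1) ||
      stats::sd(vb) <= tol * (abs(mean(vb)) + 1)) {
    message("temporal_correlation: constant smoothed series; ",
            "correlation undefined")
    return(NA_real_)
  }
  stats::cor(va, vb)
}
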
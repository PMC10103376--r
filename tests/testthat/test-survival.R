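test_that("life table reproduces the hand-worked actuarial example", {
  # 4 subjects: deaths at 1 and 2, censored at 1.5 and 3, yearly
  # intervals; times on a boundary close their interval.
  # interval 1: risk 4, d 1, c 0, eff 4   -> S = 3/4
  # interval 2: risk 3, d 1, c 1, eff 2.5 -> S = 0.75 * 0.6 = 0.45
  # interval 3: risk 1, d 0, c 1, eff 0.5 -> S = 0.45
  lt <- life_table(c(1, 2, 1.5, 3), c(TRUE, TRUE, FALSE, FALSE),
                   interval_width = 1)
  expect_equal(lt$at_risk, c(4, 3, 1))
  expect_equal(lt$deaths, c(1, 1, 0))
  expect_equal(lt$censored, c(0, 1, 1))
  expect_equal(lt$eff_at_risk, c(4, 2.5, 0.5))
  expect_equal(lt$surv, c(0.75, 0.45, 0.45), tolerance = 1e-12)
})

test_that("without censoring the life table matches the empirical survivor", {
  set.seed(51)
  times <- round(rexp(80, 1 / 3), 2)
  lt <- life_table(times, rep(TRUE, 80), interval_width = 0.25)
  emp <- vapply(lt$end, function(t) mean(times > t), numeric(1))
  expect_equal(lt$surv, emp, tolerance = 1e-12)
  expect_true(all(diff(lt$surv) <= 1e-12))  # non-increasing
  # cross-check against the Kaplan-Meier estimator at the interval ends
  km <- survival::survfit(survival::Surv(times, rep(1, 80)) ~ 1)
  km_at <- summary(km, times = lt$end, extend = TRUE)$surv
  expect_equal(lt$surv, km_at, tolerance = 1e-12)
})

test_that("life table edge cases behave as specified", {
  one <- life_table(c(0.1, 0.2, 0.3), c(TRUE, TRUE, TRUE),
                    interval_width = 1)
  expect_equal(one$surv, 0)
  expect_warning(lt <- life_table(c(1, 2), c(FALSE, FALSE)), "censored")
  expect_true(all(lt$surv == 1))
  expect_error(life_table(numeric(0), logical(0)), "empty")
})

test_that("plateau-exponential inverts a noiseless curve exactly", {
  tgrid <- seq(0.5, 20, by = 0.5)
  fake <- structure(
    data.frame(start = tgrid - 0.5, end = tgrid,
               surv = plateau_exponential(tgrid, 0.3, 2.5)),
    class = c("life_table", "data.frame"))
  fit <- fit_plateau_exponential(fake)
  expect_equal(fit$pi, 0.3, tolerance = 1e-4)
  expect_equal(fit$t_half, 2.5, tolerance = 1e-3)
  # the model satisfies S(t_half) = 1/2 exactly when the plateau is 0
  expect_equal(plateau_exponential(7.7, 0, 7.7), 0.5)
})

test_that("plateau and half-life are recovered within 3 bootstrap SEs", {
  spec <- survival_cohort_spec(
    data.frame(label = c("tail37", "nofrac"),
               pi = c(0.374, 0), t_half = c(3, 1.9),
               n = c(4000, 4000), censor_rate = 0),
    horizon = 30, seed = 52)
  coh <- generate_survival_cohort(spec)
  a <- coh[coh$stratum == "tail37", ]
  fa <- fit_plateau_exponential(a$time, a$event, boot_B = 100, seed = 53)
  expect_lt(abs(fa$pi - 0.374), 3 * fa$se_pi)

  b <- coh[coh$stratum == "nofrac", ]
  fb <- fit_plateau_exponential(b$time, b$event, boot_B = 100, seed = 54)
  expect_lt(abs(fb$t_half - 1.9), 3 * fb$se_t_half)
  expect_lt(fb$pi, 0.02)

  # raw-time likelihood mode agrees with the curve fit
  fm <- fit_plateau_exponential(a$time, a$event, mode = "mle")
  expect_equal(fm$pi, 0.374, tolerance = 0.05)
  expect_equal(fm$t_half, 3, tolerance = 0.25)
})

test_that("weak identifiability beyond the horizon raises a warning", {
  spec <- survival_cohort_spec(
    data.frame(label = "s", pi = 0.5, t_half = 6, n = 300,
               censor_rate = 0),
    horizon = 4, seed = 55)
  coh <- generate_survival_cohort(spec)
  expect_warning(fit_plateau_exponential(coh$time, coh$event),
                 "weakly identified")
})

test_that("stratified comparison favors the null under a common curve", {
  daics <- vapply(1:11, function(s) {
    spec <- survival_cohort_spec(
      data.frame(label = c("a", "b"), pi = 0.2, t_half = 3, n = 92,
                 censor_rate = 0),
      horizon = 12, seed = 100 + s)
    coh <- generate_survival_cohort(spec)
    suppressWarnings(suppressMessages(
      compare_stratified(coh$time, coh$event, coh$stratum)))$delta_aic
  }, numeric(1))
  expect_lte(median(evidence_ratio(daics)), 1)
})

test_that("stratified comparison detects separated half-lives", {
  spec <- survival_cohort_spec(
    data.frame(label = c("fast", "slow"), pi = 0, t_half = c(1.9, 9),
               n = 200, censor_rate = 0),
    horizon = 12, seed = 56)
  coh <- generate_survival_cohort(spec)
  cmp <- suppressWarnings(compare_stratified(coh$time, coh$event,
                                             coh$stratum))
  expect_lt(cmp$p_logrank, 0.001)
  expect_gt(cmp$er, 1)
  expect_lt(cmp$p_f, 0.05)

  # duplicated stratum: log-rank statistic is essentially zero
  dup <- rbind(coh[coh$stratum == "fast", ], coh[coh$stratum == "fast", ])
  dup$stratum <- rep(c("x", "y"), each = sum(coh$stratum == "fast"))
  cmp2 <- suppressWarnings(compare_stratified(dup$time, dup$event,
                                              dup$stratum))
  expect_lt(cmp2$logrank_chisq, 1e-8)

  expect_warning(
    expect_error(
      compare_stratified(c(coh$time[1:5], 1), c(rep(TRUE, 5), FALSE),
                         c(rep("a", 5), "b")),
      "at least 2 strata"),
    "no events")
})

test_that("half-life ratios come out of the fitted pair", {
  spec <- survival_cohort_spec(
    data.frame(label = c("fast", "slow"), pi = 0, t_half = c(1.9, 9),
               n = c(1500, 1500), censor_rate = 0),
    horizon = 40, seed = 57)
  coh <- generate_survival_cohort(spec)
  fa <- suppressWarnings(fit_plateau_exponential(
    coh$time[coh$stratum == "fast"], coh$event[coh$stratum == "fast"]))
  fb <- suppressWarnings(fit_plateau_exponential(
    coh$time[coh$stratum == "slow"], coh$event[coh$stratum == "slow"]))

  same <- half_life_ratio(fa, fa, B = 0)
  expect_equal(same$ratio, 1)

  fb2 <- fb; fb2$t_half <- 2 * fb$t_half
  expect_equal(half_life_ratio(fb, fb2, B = 0)$ratio, 2)

  hr <- half_life_ratio(fa, fb, B = 100, seed = 58)
  expect_gte(9 / 1.9, hr$ci[1] * 0.9)
  expect_lte(9 / 1.9, hr$ci[2] * 1.1)
  expect_equal(hr$ratio, 9 / 1.9, tolerance = 0.2)

  bad <- fa; bad$t_half <- 0
  expect_error(half_life_ratio(bad, fb), "degenerate")
})
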
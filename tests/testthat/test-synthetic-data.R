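test_that("a degenerate compartment mixture makes every GFP+ event TA", {
  spec <- cohort_spec(
    groups = c(control = 3L),
    load_model = list(control = list(family = "point", value = 20)),
    compartment_mix = list(control = c(qSC = 0, pSC = 0, TA = 1, TD = 0)),
    events_per_sample = 2000, seed = 71)
  coh <- generate_flow_cohort(spec, control_events = 1000)
  expect_true(all(coh$truth$TA == coh$truth$n_gfp))
  expect_true(all(coh$truth$qSC + coh$truth$pSC + coh$truth$TD == 0))
})

test_that("per-mouse loads follow the group load model", {
  spec <- cohort_spec(
    groups = c(control = 5L),
    load_model = list(control = list(family = "normal", mu = 0.33,
                                     sigma = 0.09)),
    compartment_mix = list(control = c(0, 0, 1, 0)),
    events_per_sample = 1e5, seed = 72)
  coh <- generate_flow_cohort(spec, control_events = 1000)
  realized <- 100 * coh$truth$n_gfp / coh$truth$n_events
  expect_lt(abs(mean(realized) - 0.33), 3 * 0.09 / sqrt(5))

  # law of large numbers across many mice
  spec2 <- cohort_spec(
    groups = c(g = 80L),
    load_model = list(g = list(family = "exponential", beta = 0.7)),
    compartment_mix = list(g = c(0, 0, 1, 0)),
    events_per_sample = 2e4, seed = 73)
  coh2 <- generate_flow_cohort(spec2, control_events = 1000)
  realized2 <- 100 * coh2$truth$n_gfp / coh2$truth$n_events
  expect_lt(abs(mean(realized2) - 0.7), 3 * 0.7 / sqrt(80))
})

test_that("compartment truth proportions converge to the mixture", {
  mix <- c(qSC = 5.64, pSC = 22, TA = 60.7, TD = 6.07)
  mix <- mix / sum(mix)
  spec <- cohort_spec(
    groups = c(pt = 1L),
    load_model = list(pt = list(family = "point", value = 50)),
    compartment_mix = list(pt = mix),
    events_per_sample = 1e5, seed = 74)
  coh <- generate_flow_cohort(spec, control_events = 1000)
  tr <- coh$truth
  props <- unlist(tr[, c("qSC", "pSC", "TA", "TD")]) / tr$n_gfp
  for (i in 1:4)
    expect_lt(abs(props[i] - mix[i]),
              3 * sqrt(mix[i] * (1 - mix[i]) / tr$n_gfp))
})

test_that("flow generation is byte-identical under a fixed seed", {
  spec <- cohort_spec(groups = c(control = 2L),
                      events_per_sample = 5000, seed = 75)
  a <- generate_flow_cohort(spec, control_events = 2000)
  b <- generate_flow_cohort(spec, control_events = 2000)
  expect_identical(a, b)
})

test_that("unresolvable positive loads are refused with a diagnostic", {
  spec <- cohort_spec(groups = c(control = 2L), events_per_sample = 1000,
                      seed = 76)
  expect_error(generate_flow_cohort(spec), "events_per_sample")
  # a point mass at zero (tumor-free group) is legitimate at any depth
  spec0 <- cohort_spec(
    groups = c(`vegf-only` = 2L),
    load_model = list(`vegf-only` = list(family = "point", value = 0)),
    compartment_mix = list(`vegf-only` = NULL),
    events_per_sample = 1000, seed = 76)
  coh <- generate_flow_cohort(spec0, control_events = 500)
  expect_true(all(coh$truth$n_gfp == 0))
})

test_that("cohort specs validate their invariants", {
  expect_error(cohort_spec(compartment_mix = list(
    control = c(0.5, 0.2, 0.2, 0.2), pcl = c(0, 0, 1, 0),
    `pcl-vegf` = c(0, 0, 1, 0), `vegf-only` = NULL)), "summing to 1")
  expect_error(cohort_spec(load_model = list(
    control = list(family = "normal", mu = -1, sigma = 0.1),
    pcl = list(family = "normal", mu = 0.2, sigma = 0.1),
    `pcl-vegf` = list(family = "exponential", beta = 0.7),
    `vegf-only` = list(family = "point", value = 0))), "nonnegative")
  expect_error(survival_cohort_spec(
    data.frame(label = "x", pi = 1.2, t_half = 1, n = 10,
               censor_rate = 0)))
  expect_error(expression_cohort_spec(n_samples = 4), "n_samples")
})

test_that("survival times follow the plateau-exponential law", {
  # no plateau, half-life 1: the median event time is one half-life
  spec <- survival_cohort_spec(
    data.frame(label = "s", pi = 0, t_half = 1, n = 40000,
               censor_rate = 0),
    horizon = 50, seed = 77)
  coh <- generate_survival_cohort(spec)
  expect_equal(median(coh$time), 1, tolerance = 0.03)

  # plateau 0.374: the fraction alive at a long horizon matches
  spec2 <- survival_cohort_spec(
    data.frame(label = "s", pi = 0.374, t_half = 1, n = 10000,
               censor_rate = 0),
    horizon = 30, seed = 78)
  coh2 <- generate_survival_cohort(spec2)
  p_alive <- mean(!coh2$event)
  expect_lt(abs(p_alive - 0.374), 3 * sqrt(0.374 * 0.626 / 10000) + 0.001)

  # pointwise convergence of the empirical curve to S(t)
  tgrid <- c(0.5, 1, 2, 4, 8)
  emp <- vapply(tgrid, function(t) mean(coh2$time > t), numeric(1))
  expect_equal(emp, plateau_exponential(tgrid, 0.374, 1), tolerance = 0.02)

  # plateau 1: nobody ever fails
  spec3 <- survival_cohort_spec(
    data.frame(label = "s", pi = 1, t_half = 1, n = 100,
               censor_rate = 0.2),
    horizon = 10, seed = 79)
  expect_warning(coh3 <- generate_survival_cohort(spec3), "censored")
  expect_false(any(coh3$event))

  expect_identical(generate_survival_cohort(spec2),
                   generate_survival_cohort(spec2))
})

test_that("expression cohorts encode the latent signatures they claim", {
  spec <- expression_cohort_spec(seed = 80)
  coh <- generate_expression_cohort(spec)
  expect_equal(dim(coh$expression), c(771L, 184L))
  expect_equal(as.integer(table(coh$truth$label)),
               as.integer(round(c(0.10, 0.15, 0.60, 0.15) * 184)))

  # in-set means shift in the direction the label dictates
  fate <- colMeans(coh$expression[coh$gene_sets[[1]], ])
  lab <- as.character(coh$truth$label)
  expect_lt(max(fate[lab %in% c("qSC", "pSC")]),
            min(fate[lab %in% c("TA", "TD")]))

  expect_identical(generate_expression_cohort(spec),
                   generate_expression_cohort(spec))

  # eight samples: every quartile bin holds exactly two
  spec8 <- expression_cohort_spec(n_samples = 8, seed = 81)
  coh8 <- generate_expression_cohort(spec8)
  calls8 <- stratify_cohort(coh8$expression, coh8$gene_sets)
  expect_equal(as.integer(table(calls8$q_fate)), rep(2L, 4))
  expect_equal(as.integer(table(calls8$q_prolif)), rep(2L, 4))

  expect_error(expression_cohort_spec(
    gene_sets = list(A = character(0), B = "g1")), "empty gene set")
})
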
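test_that("FMO background gate places the threshold at the background quantile", {
  ctl <- make_events(1:1000, "Ki67", role = "FMO-control")
  g <- fmo_background_gate(ctl, "Ki67")
  # brute-force oracle: smallest sorted value with at most 3% strictly above
  xs <- sort(1:1000)
  ora <- xs[min(which(vapply(seq_along(xs),
                             function(i) mean(xs > xs[i]) <= 0.03,
                             logical(1))))]
  expect_identical(g$threshold, ora)
  expect_identical(g$threshold, 970L)
  expect_equal(g$percent_positive, 3)

  big <- make_events(seq_len(100000), "Ki67", role = "FMO-control")
  gb <- fmo_background_gate(big, "Ki67")
  # exactly 3% of the control is called positive (strictly above)
  expect_equal(sum(seq_len(100000) > gb$threshold), 3000)
  expect_equal(gb$percent_positive, 3)

  const <- make_events(rep(7, 500), "Ki67", role = "FMO-control")
  gc <- fmo_background_gate(const, "Ki67")
  expect_equal(gc$threshold, 7)
  expect_equal(gc$percent_positive, 0)
})

test_that("FMO gate guards its preconditions", {
  ctl <- make_events(1:10, "Ki67", role = "FMO-control")
  expect_warning(fmo_background_gate(ctl, "Ki67"), "unstable")
  exp_tbl <- make_events(1:100, "Ki67")
  expect_error(fmo_background_gate(exp_tbl, "Ki67"), "FMO-control")
  fmo <- make_events(1:100, "Ki67", role = "FMO-control")
  expect_error(fmo_background_gate(fmo, "GFP"), "not present")
  expect_error(fmo_background_gate(make_events(1:100, "Ki67",
                                               role = "FMO-control"),
                                   "Ki67", background = 1.5), "0, 1")
  # the fraction of control events strictly above the threshold stays in
  # [background - 1/n, background] across sample sizes
  for (n in c(37, 100, 1234)) {
    ctl_n <- make_events(sort(runif(n)), "Ki67", role = "FMO-control")
    g <- suppressWarnings(fmo_background_gate(ctl_n, "Ki67"))
    frac <- g$percent_positive / 100
    expect_lte(frac, 0.03 + 1e-12)
    expect_gte(frac, 0.03 - 1 / n - 1e-12)
  }
})

test_that("Overton subtraction recovers constructed positive fractions", {
  set.seed(41)
  # self-subtraction is exactly zero
  s <- make_events(rlnorm(2000), "GFP")
  expect_equal(overton_subtraction(s, s, "GFP")$percent_positive, 0)

  # disjoint supports: everything positive
  ctl <- make_events(runif(2000, 0, 1), "GFP", role = "biological-control")
  hi <- make_events(runif(2000, 5, 6), "GFP")
  expect_equal(overton_subtraction(hi, ctl, "GFP")$percent_positive, 100)

  # 50:50 mixture of control-like and clearly shifted events; the oracle
  # is the direct count of shifted events
  n <- 4000
  base <- runif(n, 0, 1)
  shifted <- runif(n, 5, 6)
  mix <- make_events(c(base, shifted), "GFP")
  ctl2 <- make_events(runif(2 * n, 0, 1), "GFP",
                      role = "biological-control")
  pct <- overton_subtraction(mix, ctl2, "GFP")$percent_positive
  expect_equal(pct, 50, tolerance = 0.05)

  # control exceeding the sample everywhere returns 0, not negative
  lo <- make_events(runif(1000, 0, 0.2), "GFP")
  expect_gte(overton_subtraction(lo, ctl, "GFP")$percent_positive, 0)

  # degenerate: single occupied bin
  a <- make_events(rep(1, 50), "GFP")
  expect_error(overton_subtraction(a, a, "GFP"), "occupied bins")
})

test_that("Overton matches a brute-force per-bin oracle and its invariances", {
  set.seed(42)
  for (rep in 1:5) {
    xs <- c(rlnorm(300), rlnorm(100, 2))
    xc <- rlnorm(300)
    breaks <- seq(min(xs, xc), max(xs, xc), length.out = 65)
    got <- overton_subtraction(make_events(xs, "GFP"),
                               make_events(xc, "GFP",
                                           role = "biological-control"),
                               "GFP", bins = breaks)$percent_positive
    expect_equal(got, overton_brute(xs, xc, breaks), tolerance = 1e-10)
    expect_gte(got, 0)
    expect_lte(got, 100)
    # invariance under a strictly monotone relabeling of the axis with
    # breaks mapped accordingly
    tr <- function(v) log(v + 1)
    got_tr <- overton_subtraction(make_events(tr(xs), "GFP"),
                                  make_events(tr(xc), "GFP",
                                              role = "biological-control"),
                                  "GFP", bins = tr(breaks))$percent_positive
    expect_equal(got_tr, got, tolerance = 1e-10)
  }
})

test_that("maximum difference gate finds the KS location", {
  ones <- make_events(rep(1, 100), "GFP", role = "biological-control")
  twos <- make_events(rep(2, 100), "GFP")
  g <- max_difference_gate(twos, ones, "GFP")
  expect_gte(g$threshold, 1)
  expect_lt(g$threshold, 2)
  expect_equal(g$percent_positive, 100)
  expect_false(g$degenerate)

  same <- max_difference_gate(ones, ones, "GFP")
  expect_equal(same$percent_positive, 0)
  expect_true(same$degenerate)

  set.seed(43)
  xc <- runif(400, 0, 1)
  xs <- runif(400, 0.5, 1.5)
  got <- max_difference_gate(make_events(xs, "GFP"),
                             make_events(xc, "GFP",
                                         role = "biological-control"),
                             "GFP")
  ora <- maxdiff_brute(xs, xc)
  expect_equal(got$threshold, ora$threshold)
})

test_that("uniform shift test detects dominance and crossing CDFs", {
  set.seed(44)
  xc <- rnorm(500, 10, 1)
  ctl <- make_events(xc, "GFP", role = "biological-control")
  expect_true(uniform_shift_test(make_events(xc + 2, "GFP"), ctl, "GFP"))
  expect_true(uniform_shift_test(make_events(xc, "GFP"), ctl, "GFP"))
  # heavier low and high tails: CDFs cross; verify by direct comparison
  xs <- c(rnorm(250, 7, 1), rnorm(250, 13, 1))
  grid <- sort(c(xs, xc))
  crosses <- any(ecdf(xs)(grid) > ecdf(xc)(grid) + 0.2) &&
    any(ecdf(xs)(grid) < ecdf(xc)(grid) - 0.2)
  expect_true(crosses)
  expect_false(uniform_shift_test(make_events(xs, "GFP"), ctl, "GFP"))
})

test_that("the dispatch rule picks the method the controls dictate", {
  set.seed(45)
  fmo <- make_events(rlnorm(2000), "GFP", role = "FMO-control")
  s <- make_events(rlnorm(2000, 1), "GFP")
  expect_identical(select_gating_method(s, fmo, "GFP")$method, "fmo-3pct")

  bio <- make_events(rnorm(1000, 10, 1), "GFP", role = "biological-control")
  shifted <- make_events(rnorm(1000, 12, 1), "GFP")
  expect_identical(select_gating_method(shifted, bio, "GFP")$method,
                   "overton")

  crossing <- make_events(c(rnorm(500, 7, 1), rnorm(500, 13, 1)), "GFP")
  expect_identical(select_gating_method(crossing, bio, "GFP")$method,
                   "max-difference")

  expect_error(select_gating_method(s, NULL, "GFP"), "no control")
  expect_error(select_gating_method(s, s, "GFP"), "role")
})

test_that("2D quadrant gating partitions every event exactly once", {
  gx <- gate_set("Ki67", 10, "fmo-3pct")
  gy <- gate_set("aCasp3", 10, "fmo-3pct")

  low <- make_events2(runif(100, 0, 5), runif(100, 0, 5))
  expect_true(all(apply_gates_2d(low, gx, gy) == "-/-"))

  high <- make_events2(runif(100, 20, 30), runif(100, 20, 30))
  expect_true(all(apply_gates_2d(high, gx, gy) == "+/+"))

  # four constructed clusters, 25 events per quadrant
  clus <- make_events2(c(runif(25, 0, 5), runif(25, 15, 20),
                         runif(25, 0, 5), runif(25, 15, 20)),
                       c(runif(25, 0, 5), runif(25, 0, 5),
                         runif(25, 15, 20), runif(25, 15, 20)))
  expect_equal(as.integer(table(apply_gates_2d(clus, gx, gy))),
               c(25, 25, 25, 25))

  set.seed(46)
  for (rep in 1:5) {
    ev <- make_events2(rlnorm(200, 2, 1), rlnorm(200, 2, 1))
    labs <- apply_gates_2d(ev, gx, gy)
    expect_equal(sum(table(labs)), 200)
    expect_false(anyNA(labs))
  }
  expect_error(apply_gates_2d(low, gx, gx), "distinct")
})
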
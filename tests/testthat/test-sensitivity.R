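test_that("one-way sweeps evaluate the engine directly at the extremes", {
  abl <- fixture_abl()
  sp <- param_spec("retreatment_rate", 0.05, 0.25)
  sw <- one_way_sweep(abl, sp, steps = 5)
  lo <- intervention_total(set_param(abl, sp$path, 0.05),
                           perspective("societal"), "raw")$grand_total
  hi <- intervention_total(set_param(abl, sp$path, 0.25),
                           perspective("societal"), "raw")$grand_total
  expect_equal(sw$totals$grand_total[1], lo)
  expect_equal(sw$totals$grand_total[5], hi)
  expect_equal(sw$range_width, hi - lo)
  # the recurrence range brackets the headline 15% total
  mid <- intervention_total(abl, perspective("societal"), "raw")$grand_total
  expect_lt(lo, mid); expect_gt(hi, mid)
  # and, in fidelity mode, brackets the published 1,560.06
  swf <- one_way_sweep(abl, sp, steps = 2, mode = "fidelity")
  expect_lt(swf$totals$grand_total[1], 1560.06)
  expect_gt(swf$totals$grand_total[2], 1560.06)
})

test_that("degenerate and increasing sweeps behave as stated", {
  abl <- fixture_abl()
  flat <- one_way_sweep(abl, param_spec("indirect.hourly_wage", 14.05, 14.05),
                        steps = 4)
  expect_equal(flat$range_width, 0)
  expect_equal(unique(flat$totals$grand_total),
               flat$totals$grand_total[1])
  tt <- fixture_tt()
  inc <- one_way_sweep(
    tt, param_spec("material_items[Gauze].weighted_cost_override", 0.5, 5),
    steps = 6)
  expect_true(all(diff(inc$totals$grand_total) > 0))
  expect_error(one_way_sweep(tt, param_spec("no.such.path", 0, 1)),
               "does not resolve")
})

test_that("tornado ranks parameters by induced range, ties by path", {
  tt <- fixture_tt()
  tor <- tornado(tt, list(
    param_spec("material_items[Gauze].weighted_cost_override", 0.5, 1.5),
    param_spec("facility.stay_days", 1.5, 3.5)))
  expect_equal(tor$parameter[1], "facility.stay_days")
  expect_gt(tor$range_width[1], tor$range_width[2])
  # brute-force oracle for the widths
  eval_at <- function(path, v)
    intervention_total(set_param(tt, path, v), perspective("societal"),
                       "raw")$grand_total
  expect_equal(tor$range_width[1],
               eval_at("facility.stay_days", 3.5) -
                 eval_at("facility.stay_days", 1.5))
  one <- tornado(tt, list(param_spec("retreatment_rate", 0, 0.2)))
  expect_equal(nrow(one), 1L)
  fixed <- tornado(tt, list(
    param_spec("indirect.hourly_wage", 14.05, 14.05, "fixed",
               list(value = 14.05)),
    param_spec("facility.stay_days", 2.40, 2.40, "fixed",
               list(value = 2.40))))
  expect_equal(fixed$range_width, c(0, 0))
  # ties broken lexicographically by path
  expect_equal(fixed$parameter,
               sort(c("indirect.hourly_wage", "facility.stay_days")))
})

test_that("Monte Carlo is reproducible and degenerates correctly", {
  abl <- fixture_abl()
  specs <- list(param_spec("retreatment_rate", 0.05, 0.25),
                param_spec("indirect.hourly_wage", 10, 18, "triangular"))
  a <- monte_carlo(abl, specs, n = 50, seed = 123)
  b <- monte_carlo(abl, specs, n = 50, seed = 123)
  expect_identical(a$totals, b$totals)
  expect_identical(a$quantiles, b$quantiles)
  expect_false(identical(
    a$totals, monte_carlo(abl, specs, n = 50, seed = 124)$totals))
  # per-spec substreams: appending a spec leaves existing draws untouched
  a1 <- monte_carlo(abl, specs[1], n = 50, seed = 123)
  d0 <- abl; d0$indirect$hourly_wage <- 0
  a1w <- monte_carlo(d0, specs[1], n = 50, seed = 123)
  expect_equal(order(a1$totals), order(a1w$totals))  # same r draws
  # all-fixed specs reproduce the deterministic total with zero spread
  fx <- list(param_spec("retreatment_rate", 0.15, 0.15, "fixed",
                        list(value = 0.15)))
  mc1 <- monte_carlo(abl, fx, n = 1, seed = 5)
  det <- intervention_total(abl, perspective("societal"), "raw")$grand_total
  expect_equal(mc1$mean_total, det)
  expect_equal(mc1$sd_total, 0)
  mc9 <- monte_carlo(abl, fx, n = 9, seed = 5)
  expect_equal(mc9$sd_total, 0)
  expect_equal(mc9$mean_total, det)
  expect_true(all(diff(sort(a$quantiles)) >= 0))
})

test_that("draws respect their distributions' support", {
  abl <- fixture_abl()
  tri <- monte_carlo(abl, list(param_spec("retreatment_rate", 0.05, 0.25,
                                          "triangular")),
                     n = 200, seed = 42)
  r_implied <- range(tri$totals)
  lo <- intervention_total(set_param(abl, "retreatment_rate", 0.05),
                           perspective("societal"), "raw")$grand_total
  hi <- intervention_total(set_param(abl, "retreatment_rate", 0.25),
                           perspective("societal"), "raw")$grand_total
  expect_gte(r_implied[1], lo); expect_lte(r_implied[2], hi)
  # truncated normal never proposes a negative wage
  tn <- monte_carlo(abl, list(param_spec("indirect.hourly_wage", 0, 30,
                                         "normal-truncated-at-zero",
                                         list(mean = 2, sd = 5))),
                    n = 200, seed = 42)
  expect_true(all(is.finite(tn$totals)))
  expect_error(param_spec("x", 0, 1, "normal-truncated-at-zero",
                          list(sd = -1)), "sd must be >= 0")
  expect_error(param_spec("x", 1, 0), "low <= high")
  expect_error(param_spec("x", 0, 1, "lognormal"), "unknown distribution")
})

test_that("the Monte Carlo mean converges to the analytic mean for a linear parameter", {
  abl <- fixture_abl()
  # the total is linear in r, so E[T(r)] = T(E[r]) = T(0.15) for a
  # uniform(0.05, 0.25) recurrence rate
  mc <- monte_carlo(abl, list(param_spec("retreatment_rate", 0.05, 0.25)),
                    n = 2000, seed = 77)
  analytic <- intervention_total(abl, perspective("societal"),
                                 "raw")$grand_total
  se <- mc$sd_total / sqrt(mc$n)
  expect_lt(abs(mc$mean_total - analytic), 3 * se)
})
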
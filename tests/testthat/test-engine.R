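test_that("item costs follow the weighted-override / flat / product rules", {
  expect_equal(item_cost(cost_items("levothyroxine", unit_cost = 47.63)),
               47.63)                         # flat item, no quantity
  expect_equal(item_cost(cost_items("x", quantity = 0, unit_cost = 100)), 0)
  expect_equal(item_cost(cost_items("stay", quantity = 2.40,
                                    unit_cost = 674.00)), 1617.60)
  # the printed per-patient cost wins over quantity * unit price
  expect_equal(item_cost(cost_items("y", quantity = 3, unit_cost = 10,
                                    weighted_cost_override = 12.5)), 12.5)
})

test_that("phase sums reproduce the transcribed table totals exactly", {
  tt <- fixture_tt()
  expect_equal(phase_cost(tt$prehosp_items), 281.80)
  expect_equal(phase_cost(tt$material_items), 199.54)
  expect_equal(phase_cost(cost_items()), 0)
  expect_equal(phase_cost(tt$prehosp_items, override = 50), 50)
})

test_that("drug categories aggregate per policy", {
  lines <- drug_lines(
    category = c("opioids", "opioids", "antibiotics", "antibiotics",
                 "other", "other", "corticosteroids"),
    drug = c("fentanyl", "remifentanil", "ceftriaxone", "cefazolin",
             "paracetamol", "saline", "cortisone"),
    cost = c(0.62, 11.97, 4.50, 0.90, 0.37, 0.18, 1.10))
  pol <- drug_policies(c("opioids", "antibiotics", "corticosteroids"),
                       "mean_of_alternatives")
  got <- drug_cost(lines, pol)
  expect_equal(round_cents(mean(c(0.62, 11.97))), 6.30)
  expect_equal(round_cents(mean(c(4.50, 0.90))), 2.70)
  # single-line category under mean is that line; "other" always sums
  expect_equal(got, 6.295 + 2.70 + 1.10 + 0.55)
  expect_error(drug_cost(drug_lines("opioids", "f", 1, 1), drug_policies()),
               "no aggregation policy")
})

test_that("facility costs honor printed values and duration-rate products by mode", {
  expect_equal(
    facility_cost(facility_params(stay_days = 2.00,
                                  stay_rate_per_day = 674))$stay_cost,
    1348.00)
  # the OR minute rate implied by one surgical table transfers to the other
  rate <- 1685.28 / 82.50
  hemi_or <- facility_cost(facility_params(
    or_minutes = 66.43, or_rate_per_minute = rate, stay_days = 0))$or_cost
  expect_lt(abs(hemi_or - 1356.98), 0.05)  # the two tables imply one rate
  expect_equal(facility_cost(facility_params(stay_days = 0))$stay_cost, 0)
  expect_error(facility_cost(facility_params(stay_days = NA,
                                             stay_rate_per_day = 5,
                                             stay_cost = NA)),
               "rate given without a duration")
  # raw mode prefers the product, fidelity the printed cost
  fp <- facility_params(stay_days = 3, stay_cost = 100,
                        stay_rate_per_day = 10)
  expect_equal(facility_cost(fp, "fidelity")$stay_cost, 100)
  expect_equal(facility_cost(fp, "raw")$stay_cost, 30)
})

test_that("staff costs sum the engagement-weighted lines", {
  expect_equal(staff_cost(fixture_abl()$staff_lines), 35.34)
  # the five-role surgical table column sums one cent under its printed total
  expect_equal(staff_cost(fixture_tt()$staff_lines), 232.47,
               tolerance = 0.02 / 232.47)
  expect_equal(staff_cost(staff_lines()), 0)
})

test_that("follow-up mixture weights courses by frequency", {
  tt_courses <- fixture_tt()$followup_courses
  mixed <- followup_expected_cost(tt_courses, "fidelity")
  expect_gte(mixed, 152.49); expect_lte(mixed, 152.50)
  one <- list(followup_course("standard", 1, cost_items(),
                              printed_total = 143.04))
  expect_equal(followup_expected_cost(one, "fidelity"), 143.04)
  abl <- list(followup_course("standard", 0.93, cost_items(),
                              printed_total = 97.97))
  expect_equal(followup_expected_cost(abl, "fidelity"), 91.11)
  bad <- list(followup_course("standard", 0.9, cost_items(), 1),
              followup_course("acute_complications", 0.6, cost_items(), 1))
  expect_error(followup_expected_cost(bad), "sum to at most 1")
})

test_that("productivity loss follows the human-capital formula", {
  tt_raw <- productivity_loss(indirect_params(
    hosp_days = 2.40, convalescence_days = 11.22, hours_lost_per_day = 5,
    hourly_wage = 14.05, caregiver_share = 0.05), "raw")
  expect_equal(tt_raw$total_days, 13.62)
  expect_equal(tt_raw$patient_loss, 13.62 * 5 * 14.05)
  expect_equal(tt_raw$total_loss, 1004.68, tolerance = 0.0005)  # 1,004.65 raw
  hemi_raw <- productivity_loss(indirect_params(
    hosp_days = 2.00, convalescence_days = 8.50, hours_lost_per_day = 5,
    hourly_wage = 14.05, caregiver_share = 0.025), "raw")
  expect_equal(hemi_raw$total_loss, 755.97, tolerance = 0.0005)  # 756.07 raw
  none <- productivity_loss(indirect_params(hosp_days = 1,
                                            convalescence_days = 4,
                                            caregiver_share = 0), "raw")
  expect_equal(none$caregiver_loss, 0)
  expect_equal(none$total_loss, none$patient_loss)
  # fidelity honors the printed terms and stays internally additive
  tt_fid <- productivity_loss(fixture_tt()$indirect, "fidelity")
  expect_identical(tt_fid$total_loss,
                   tt_fid$patient_loss + tt_fid$caregiver_loss)
  expect_equal(tt_fid$total_loss, 1004.68)
})

test_that("retreatment uplift scales by (1 + r) and rejects bad rates", {
  expect_equal(round_cents(retreatment_uplift(321.09, 0.15)), 369.25)
  expect_equal(round_cents(retreatment_uplift(35.34, 0.15)), 40.64)
  expect_equal(retreatment_uplift(123.45, 0), 123.45)
  expect_error(retreatment_uplift(1, -0.1), "rate must lie")
  expect_error(retreatment_uplift(1, 1), "rate must lie")
})

test_that("fidelity-mode grand totals reproduce the published headline figures", {
  ds <- bundled_datasets()
  soc <- lapply(ds, intervention_total, perspective("societal"), "fidelity")
  expect_equal(soc$total_thyroidectomy$grand_total, 5185.36,
               tolerance = 0.02 / 5185.36)
  expect_equal(soc$hemithyroidectomy$grand_total, 4211.92,
               tolerance = 0.02 / 4211.92)
  expect_equal(soc$thermal_ablation$grand_total, 1560.06,
               tolerance = 0.02 / 1560.06)
  opp <- lapply(ds, intervention_total,
                perspective("opportunity_cost_societal"), "fidelity")
  expect_equal(opp$hemithyroidectomy$grand_total, 4027.17)
  expect_equal(opp$thermal_ablation$grand_total, 1519.42)
  expect_equal(intervention_total(zero_dataset())$grand_total, 0)
})

test_that("grand totals are additive over their own audit components", {
  cases <- c(bundled_datasets(),
             list(s = generate_dataset(synth_config(seed = 7))$dataset))
  for (d in cases) for (p in all_perspectives()) for (m in c("fidelity", "raw")) {
    b <- intervention_total(d, p, m)
    expect_equal(b$grand_total, sum(b$audit$post_uplift[b$audit$included]),
                 tolerance = 1e-9,
                 label = paste("additivity", d$name, p$name, m))
  }
})

test_that("societal total minus personnel equals the opportunity-cost total exactly", {
  cases <- c(bundled_datasets(),
             list(s = generate_dataset(synth_config(seed = 11))$dataset))
  for (d in cases) for (m in c("fidelity", "raw")) {
    soc <- intervention_total(d, perspective("societal"), m)
    opp <- intervention_total(d, perspective("opportunity_cost_societal"), m)
    expect_equal(soc$grand_total - soc$phase_costs[["personnel"]],
                 opp$grand_total, tolerance = 1e-9,
                 label = paste("perspective algebra", d$name, m))
  }
})

test_that("the uplift acts linearly and r = 0 reproduces base totals", {
  abl <- fixture_abl()
  base <- abl; base$retreatment_rate <- 0
  for (m in c("fidelity", "raw")) {
    b0 <- intervention_total(base, perspective("societal"), m)
    br <- intervention_total(abl, perspective("societal"), m)
    # uplifted components scale by 1.15; follow-up does not
    a0 <- b0$audit; ar <- br$audit
    upl <- setdiff(a0$component, c("followup", "subtotal_adjustment"))
    for (cmp in upl) {
      expect_equal(ar$base[ar$component == cmp] * 1.15,
                   ar$post_uplift[ar$component == cmp],
                   tolerance = if (m == "fidelity") 0.005 else 1e-9,
                   label = paste("uplift", cmp, m))
      # fidelity rounds components at their boundary even for r = 0
      expect_equal(a0$base[a0$component == cmp],
                   a0$post_uplift[a0$component == cmp],
                   tolerance = if (m == "fidelity") 0.005 else 1e-9,
                   label = paste("r=0 identity", cmp, m))
    }
    expect_equal(ar$post_uplift[ar$component == "followup"],
                 ar$base[ar$component == "followup"])
  }
})

test_that("grand totals are monotone in prices, quantities and rates", {
  tt <- fixture_tt()
  base <- intervention_total(tt, perspective("societal"), "raw")$grand_total
  bumps <- list(
    c("material_items[Gauze].weighted_cost_override", 0.93, 2),
    c("prehosp_items[CBC].quantity", 1, 3),
    c("facility.stay_days", 2.40, 4),
    c("indirect.hourly_wage", 14.05, 20),
    c("indirect.convalescence_days", 11.22, 15),
    c("followup_courses[standard].frequency", 0.93, 0.929),
    c("drug_lines[Remifentanil].cost", 11.97, 15))
  for (bp in bumps) {
    up <- set_param(tt, bp[1], as.numeric(bp[3]))
    tot <- intervention_total(up, perspective("societal"), "raw")$grand_total
    cmp <- if (as.numeric(bp[3]) >= as.numeric(bp[2])) tot >= base else tot <= base
    expect_true(cmp, label = paste("monotone in", bp[1]))
  }
})

test_that("fidelity and raw mode agree within the rounding-chain bound", {
  for (d in bundled_datasets()) {
    f <- intervention_total(d, perspective("societal"), "fidelity")$grand_total
    r <- intervention_total(d, perspective("societal"), "raw")$grand_total
    expect_lt(abs(f - r) / f, 0.0015, label = paste("mode agreement", d$name))
  }
  for (s in 1:5) {
    pb <- generate_paperlike(s)
    f <- intervention_total(pb$dataset, perspective("societal"), "fidelity")$grand_total
    r <- intervention_total(pb$dataset, perspective("societal"), "raw")$grand_total
    # no printed aggregates: the modes differ only by component rounding
    expect_lt(abs(f - r), 0.05, label = paste("paperlike mode agreement", s))
  }
})

test_that("comparisons report absolute and relative savings vs the baseline", {
  ds <- bundled_datasets()
  soc <- lapply(ds, intervention_total, perspective("societal"), "fidelity")
  cmp <- compare_interventions(soc, baseline = "total_thyroidectomy")
  abl <- cmp[cmp$comparator == "thermal_ablation", ]
  expect_equal(abl$relative_saving, 1 - 1560.06 / 5185.36, tolerance = 1e-6)
  expect_equal(abl$relative_saving, 0.70, tolerance = 0.01)
  hemi_cmp <- compare_interventions(soc, baseline = "hemithyroidectomy")
  expect_gt(hemi_cmp[hemi_cmp$comparator == "thermal_ablation",
                     "relative_saving"], 0.60)
  clone <- ds$total_thyroidectomy; clone$name <- "clone"
  same <- compare_interventions(
    list(soc$total_thyroidectomy, intervention_total(clone)),
    baseline = "total_thyroidectomy")
  expect_equal(same$absolute_saving[same$comparator == "clone"], 0)
  expect_equal(same$relative_saving[same$comparator == "clone"], 0)
  mixed <- list(soc$total_thyroidectomy,
                intervention_total(ds$thermal_ablation,
                                   perspective("nhs_direct")))
  err <- tryCatch(compare_interventions(mixed, "total_thyroidectomy"),
                  error = identity)
  expect_s3_class(err, "thyrocost_comparison_error")
})
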
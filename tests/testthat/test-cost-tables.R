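test_that("validation reports all violations at once and names the mixture constraint", {
  bad <- try(intervention_dataset(
    name = "bad",
    prehosp_items = cost_items("x", quantity = -1, unit_cost = -5),
    followup_courses = list(
      followup_course("standard", 0.9, cost_items()),
      followup_course("acute_complications", 0.6, cost_items())),
    retreatment_rate = 1.2), silent = TRUE)
  expect_s3_class(attr(bad, "condition"), "thyrocost_validation_error")
  msg <- conditionMessage(attr(bad, "condition"))
  expect_match(msg, "quantity must be >= 0")
  expect_match(msg, "unit_cost must be >= 0")
  expect_match(msg, "sum to at most 1")
  expect_match(msg, "mixture")
  expect_match(msg, "retreatment_rate")
})

test_that("items need a unit cost or a weighted override, policies need overrides iff printed", {
  expect_error(
    intervention_dataset("x", prehosp_items = cost_items("a")),
    "unit_cost or weighted_cost_override")
  expect_error(
    intervention_dataset("x", drug_lines = drug_lines("opioids", "f", 1, 1),
                         drug_policies = drug_policies("opioids",
                                                       "printed_override")),
    "requires override_cost")
  expect_error(
    intervention_dataset("x", drug_lines = drug_lines("opioids", "f", 1, 1),
                         drug_policies = drug_policies(
                           "opioids", "mean_of_alternatives", 3)),
    "only allowed with printed_override")
})

test_that("bundled datasets transcribe the study parameters", {
  ds <- bundled_datasets()
  expect_named(ds, c("total_thyroidectomy", "hemithyroidectomy",
                     "thermal_ablation"))
  tt <- ds$total_thyroidectomy
  expect_equal(nrow(tt$prehosp_items), 14L)
  expect_equal(tt$facility$stay_days, 2.40)
  expect_equal(tt$indirect$caregiver_share, 0.05)
  expect_equal(tt$retreatment_rate, 0)
  expect_equal(vapply(tt$followup_courses, `[[`, numeric(1), "frequency"),
               c(0.93, 0.035, 0.035))
  expect_equal(ds$hemithyroidectomy$indirect$caregiver_share, 0.025)
  expect_equal(ds$hemithyroidectomy$facility$or_minutes, 66.43)
  abl <- ds$thermal_ablation
  expect_equal(abl$retreatment_rate, 0.15)
  expect_equal(abl$indirect$caregiver_share, 0.10)
  expect_true(is.na(abl$facility$or_minutes))  # day-hospital: no OR
  for (d in ds) expect_silent(validate_dataset(d))
})

test_that("facility rates are mutually consistent across the fixtures", {
  ds <- bundled_datasets()
  stay_rates <- vapply(ds, function(d)
    d$facility$stay_cost / d$facility$stay_days, numeric(1))
  expect_lt(max(stay_rates) - min(stay_rates), 0.02)  # one bed-day rate
  or_rates <- vapply(ds[c("total_thyroidectomy", "hemithyroidectomy")],
                     function(d) d$facility$or_cost / d$facility$or_minutes,
                     numeric(1))
  expect_lt(max(or_rates) - min(or_rates), 0.02)      # one OR minute rate
})

test_that("write/load round-trips are the identity in both dialects", {
  td <- withr::local_tempdir()
  cases <- c(bundled_datasets(),
             list(synthetic = generate_dataset(synth_config(seed = 1))$dataset,
                  zero = zero_dataset()))
  for (nm in names(cases)) {
    f <- file.path(td, paste0(nm, ".yaml"))
    write_dataset(cases[[nm]], f, "yaml")
    expect_true(datasets_equal(cases[[nm]], load_dataset(f)),
                label = paste("yaml round-trip", nm))
    p <- file.path(td, paste0(nm, "_csv"))
    write_dataset(cases[[nm]], p, "csv")
    expect_true(datasets_equal(cases[[nm]], load_dataset(p)),
                label = paste("csv round-trip", nm))
  }
})

test_that("degenerate and erroneous inputs are handled on load/write", {
  td <- withr::local_tempdir()
  z <- zero_dataset()
  expect_equal(intervention_total(z)$grand_total, 0)

  # frequencies summing over 1 in a file are rejected with the constraint named
  f <- file.path(td, "overfull.yaml")
  bad <- z
  bad$followup_courses <- list(
    followup_course("standard", 0.9, cost_items(), 1),
    followup_course("acute_complications", 0.6, cost_items(), 1))
  # bypass construction-time validation to exercise the load path
  writeLines(yaml::as.yaml(thyrocost:::dataset_to_list(bad)), f)
  expect_error(load_dataset(f), "sum to at most 1")

  # malformed YAML names the parse failure
  f2 <- file.path(td, "broken.yaml")
  writeLines("name: [unclosed", f2)
  expect_error(load_dataset(f2), "parse failure")

  expect_error(load_dataset(file.path(td, "nope.yaml")), "no such file")

  # unwritable target: the parent of the destination is a regular file
  blocker <- file.path(td, "blocker"); writeLines("x", blocker)
  expect_error(suppressWarnings(
    write_dataset(z, file.path(blocker, "sub"), "csv")),
    "cannot create|not writable")
  expect_error(suppressWarnings(
    write_dataset(z, file.path(blocker, "sub.yaml"), "yaml")),
    "cannot open")
})

test_that("JSON dataset export carries 2-decimal euros plus exact cents", {
  js <- jsonlite::fromJSON(dataset_to_json(fixture_abl()),
                           simplifyVector = FALSE)
  ov <- js$phase_overrides$materials
  expect_equal(ov$eur, 575.63)
  expect_equal(ov$cents, 57563.4783, tolerance = 1e-6)
})
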
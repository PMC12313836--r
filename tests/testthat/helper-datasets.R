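# helpers shared across test files: tiny hand-built datasets with totals
# simple enough to verify by inspection

# a dataset whose every cost is zero
zero_dataset <- function() {
  intervention_dataset(
    name = "zero",
    facility = facility_params(stay_days = 0),
    followup_courses = list(followup_course("standard", 1, cost_items())),
    indirect = indirect_params())
}

# one flat pre-hospitalization item worth `total`, nothing else
flat_dataset <- function(name, total) {
  intervention_dataset(
    name = name,
    prehosp_items = cost_items(label = "flat", unit_cost = total),
    facility = facility_params(stay_days = 0))
}

fixture_tt <- function() bundled_datasets()$total_thyroidectomy
fixture_hemi <- function() bundled_datasets()$hemithyroidectomy
fixture_abl <- function() bundled_datasets()$thermal_ablation

all_perspectives <- function()
  lapply(c("nhs_direct", "societal", "opportunity_cost_societal"),
         perspective)
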
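#' Build a table of cost items
#'
#' A cost item is one driver line in a phase: a label, a mean quantity
#' consumed per patient, and either a unit cost, an already-weighted
#' per-patient cost, or both. Items with `quantity = NA` and a plain
#' `unit_cost` are "flat" costs taken as-is (the source tables print some
#' rows, e.g. replacement drug therapy, without a unit decomposition).
#'
#' @param label character vector of item labels.
#' @param quantity mean number of units per patient; may be fractional; `NA`
#'   means the item is a flat cost.
#' @param unit_cost cost per unit (EUR); `NA` allowed when
#'   `weighted_cost_override` is given.
#' @param weighted_cost_override per-patient cost (EUR) printed directly by
#'   the source table; when present it is authoritative over
#'   `quantity * unit_cost`.
#' @return a `data.frame` with one row per item.
#' @export
cost_items <- function(label = character(), quantity = NA_real_,
                       unit_cost = NA_real_,
                       weighted_cost_override = NA_real_) {
  n <- length(label)
  data.frame(
    label = as.character(label),
    quantity = rep_len(as.numeric(quantity), n),
    unit_cost = rep_len(as.numeric(unit_cost), n),
    weighted_cost_override = rep_len(as.numeric(weighted_cost_override), n),
    stringsAsFactors = FALSE
  )
}

#' @rdname cost_items
#' @param category drug macro-category; one of `"anesthetics"`, `"opioids"`,
#'   `"antibiotics"`, `"corticosteroids"`, `"other"`. Membership is always
#'   explicit, never inferred from the drug name.
#' @param drug drug name.
#' @param dose_mg dose per procedure in milligrams.
#' @param cost cost per procedure (EUR).
#' @export
drug_lines <- function(category = character(), drug = character(),
                       dose_mg = NA_real_, cost = NA_real_) {
  n <- length(drug)
  data.frame(
    category = rep_len(as.character(category), n),
    drug = as.character(drug),
    dose_mg = rep_len(as.numeric(dose_mg), n),
    cost = rep_len(as.numeric(cost), n),
    stringsAsFactors = FALSE
  )
}

DRUG_CATEGORIES <- c("anesthetics", "opioids", "antibiotics",
                     "corticosteroids", "other")
DRUG_AGGREGATIONS <- c("mean_of_alternatives", "sum_of_lines",
                       "printed_override")

#' @rdname cost_items
#' @param aggregation how a drug category's lines combine into the category
#'   cost: `"mean_of_alternatives"` (alternative agents, average cost),
#'   `"sum_of_lines"` (co-administered agents), or `"printed_override"`
#'   (the source prints a weighted category cost that cannot be recomputed
#'   from its lines).
#' @param override_cost category cost (EUR), required iff
#'   `aggregation = "printed_override"`.
#' @export
drug_policies <- function(category = character(),
                          aggregation = "mean_of_alternatives",
                          override_cost = NA_real_) {
  n <- length(category)
  data.frame(
    category = as.character(category),
    aggregation = rep_len(as.character(aggregation), n),
    override_cost = rep_len(as.numeric(override_cost), n),
    stringsAsFactors = FALSE
  )
}

#' @rdname cost_items
#' @param role professional role (physician, nurse, anesthetist, ...).
#' @param headcount mean number of professionals involved (may be
#'   fractional).
#' @export
staff_lines <- function(role = character(), headcount = NA_real_,
                        cost = NA_real_) {
  n <- length(role)
  data.frame(
    role = as.character(role),
    headcount = rep_len(as.numeric(headcount), n),
    cost = rep_len(as.numeric(cost), n),
    stringsAsFactors = FALSE
  )
}

#' Facility parameters of an intervention
#'
#' Operating-room occupation and hospital stay, each expressed as a printed
#' cost, a duration with a per-unit rate, or both (in which case the product
#' must reconcile with the printed cost within the rounding tolerance).
#' Day-hospital procedures have no operating-room component.
#'
#' @param or_minutes operating-room occupation in minutes (`NA` if none).
#' @param or_cost operating-room cost in EUR (`NA` if none).
#' @param or_rate_per_minute EUR per minute of operating-room time.
#' @param stay_days hospital stay in days.
#' @param stay_cost hospital-stay cost in EUR.
#' @param stay_rate_per_day EUR per bed-day.
#' @return a list of class `facility_params`.
#' @export
facility_params <- function(or_minutes = NA_real_, or_cost = NA_real_,
                            or_rate_per_minute = NA_real_,
                            stay_days = 0, stay_cost = NA_real_,
                            stay_rate_per_day = NA_real_) {
  structure(list(
    or_minutes = as.numeric(or_minutes), or_cost = as.numeric(or_cost),
    or_rate_per_minute = as.numeric(or_rate_per_minute),
    stay_days = as.numeric(stay_days), stay_cost = as.numeric(stay_cost),
    stay_rate_per_day = as.numeric(stay_rate_per_day)
  ), class = "facility_params")
}

FOLLOWUP_COURSES <- c("standard", "acute_complications",
                      "chronic_complications")

#' A post-operative follow-up course
#'
#' A named course (standard, or with acute/chronic complications) holding the
#' fraction of patients that follow it and its annual cost-item list. The
#' expected follow-up cost of an intervention is the frequency-weighted
#' average over its courses.
#'
#' @param name one of `"standard"`, `"acute_complications"`,
#'   `"chronic_complications"`.
#' @param frequency fraction of patients on this course, in `[0, 1]`.
#' @param items a [cost_items()] table of annual procedures.
#' @param printed_total annual course cost (EUR) as printed by the source
#'   table; authoritative in fidelity mode.
#' @return a list of class `followup_course`.
#' @export
followup_course <- function(name, frequency, items = cost_items(),
                            printed_total = NA_real_) {
  structure(list(
    name = as.character(name), frequency = as.numeric(frequency),
    items = items, printed_total = as.numeric(printed_total)
  ), class = "followup_course")
}

#' Indirect-cost (productivity-loss) parameters
#'
#' Human-capital parameters for the productivity lost by the patient and, for
#' a fraction of patients, an accompanying caregiver, during hospitalization
#' and convalescence.
#'
#' @param hosp_days days of hospitalization.
#' @param convalescence_days days of convalescence after discharge.
#' @param hours_lost_per_day working hours lost per day of treatment
#'   (study value: 5).
#' @param hourly_wage weighted hourly productivity value in EUR
#'   (study value: 14.05).
#' @param caregiver_share fraction of patients assisted by a caregiver.
#' @param printed_patient_loss,printed_caregiver_loss patient/caregiver
#'   losses (EUR) as printed by the source; authoritative in fidelity mode.
#' @return a list of class `indirect_params`.
#' @export
indirect_params <- function(hosp_days = 0, convalescence_days = 0,
                            hours_lost_per_day = 5, hourly_wage = 14.05,
                            caregiver_share = 0,
                            printed_patient_loss = NA_real_,
                            printed_caregiver_loss = NA_real_) {
  structure(list(
    hosp_days = as.numeric(hosp_days),
    convalescence_days = as.numeric(convalescence_days),
    hours_lost_per_day = as.numeric(hours_lost_per_day),
    hourly_wage = as.numeric(hourly_wage),
    caregiver_share = as.numeric(caregiver_share),
    printed_patient_loss = as.numeric(printed_patient_loss),
    printed_caregiver_loss = as.numeric(printed_caregiver_loss)
  ), class = "indirect_params")
}

#' Assemble and validate an intervention cost dataset
#'
#' The complete declarative description of one treatment's cost drivers:
#' phase-partitioned item lists, drug lines with category aggregation
#' policies, personnel lines, facility parameters, follow-up courses,
#' indirect-cost parameters, a retreatment rate, optional phase overrides
#' (used when a printed aggregate cannot be reconstructed from item rows),
#' and optional printed aggregates kept as reconciliation metadata.
#'
#' @param name unique identifier of the intervention.
#' @param prehosp_items,material_items [cost_items()] tables for the
#'   pre-hospitalization and materials phases.
#' @param drug_lines a [drug_lines()] table.
#' @param drug_policies a [drug_policies()] table covering every category
#'   present in `drug_lines`.
#' @param staff_lines a [staff_lines()] table.
#' @param facility a [facility_params()] object.
#' @param followup_courses list of [followup_course()] objects; frequencies
#'   must sum to at most 1 (any residual fraction incurs no follow-up cost).
#' @param indirect an [indirect_params()] object.
#' @param retreatment_rate fraction of patients needing the procedure again,
#'   in `[0, 1)`; their cost is folded in as a multiplicative `(1 + r)`
#'   uplift.
#' @param phase_overrides named list of flat phase costs (EUR) that replace
#'   item sums (`prehospitalization`, `drugs`, `materials`, plus
#'   `followup_residual`, a flat addition to the follow-up mixture).
#' @param printed named list of printed aggregates used by fidelity mode and
#'   reconciliation (`prehospitalization`, `drugs`, `materials`, `personnel`,
#'   `procedure_subtotal`, `followup_subtotal`, `grand_total`,
#'   `materials_table_total`).
#' @param validate check all invariants (raise an error listing every
#'   violation) before returning.
#' @return a list of class `intervention_dataset`.
#' @seealso [bundled_datasets()], [intervention_total()], [load_dataset()]
#' @export
intervention_dataset <- function(name,
                                 prehosp_items = cost_items(),
                                 drug_lines = thyrocost::drug_lines(),
                                 drug_policies = thyrocost::drug_policies(),
                                 material_items = cost_items(),
                                 staff_lines = thyrocost::staff_lines(),
                                 facility = facility_params(),
                                 followup_courses = list(),
                                 indirect = indirect_params(),
                                 retreatment_rate = 0,
                                 phase_overrides = list(),
                                 printed = list(),
                                 validate = TRUE) {
  d <- structure(list(
    name = as.character(name),
    prehosp_items = prehosp_items,
    drug_lines = drug_lines,
    drug_policies = drug_policies,
    material_items = material_items,
    staff_lines = staff_lines,
    facility = facility,
    followup_courses = followup_courses,
    indirect = indirect,
    retreatment_rate = as.numeric(retreatment_rate),
    phase_overrides = phase_overrides,
    printed = printed
  ), class = "intervention_dataset")
  if (validate) validate_dataset(d) else d
}

#' Validate an intervention dataset
#'
#' Checks every structural invariant and raises a single error (condition
#' class `thyrocost_validation_error`) listing all violations at once.
#' Reconciliation of printed aggregates against recomputed ones is *not*
#' validation — it is warning-level by design, see [reconcile_dataset()].
#'
#' @param d an [intervention_dataset()].
#' @return `d`, invisibly unchanged, if valid.
#' @export
validate_dataset <- function(d) {
  stopifnot(inherits(d, "intervention_dataset"))
  bad <- character()
  note <- function(msg) bad <<- c(bad, msg)

  chk_items <- function(items, what) {
    if (nrow(items) == 0L) return(invisible())
    q <- items$quantity; uc <- items$unit_cost; wo <- items$weighted_cost_override
    if (any(!is.na(q) & q < 0))
      note(sprintf("%s: quantity must be >= 0 when present", what))
    if (any(!is.na(uc) & uc < 0)) note(sprintf("%s: unit_cost must be >= 0", what))
    if (any(!is.na(wo) & wo < 0))
      note(sprintf("%s: weighted_cost_override must be >= 0", what))
    if (any(is.na(uc) & is.na(wo)))
      note(sprintf("%s: each item needs unit_cost or weighted_cost_override", what))
  }
  chk_items(d$prehosp_items, "prehosp_items")
  chk_items(d$material_items, "material_items")

  dl <- d$drug_lines
  if (nrow(dl) > 0L) {
    if (any(!dl$category %in% DRUG_CATEGORIES))
      note(sprintf("drug_lines: unknown category (allowed: %s)",
                   paste(DRUG_CATEGORIES, collapse = ", ")))
    if (any(!is.na(dl$dose_mg) & dl$dose_mg < 0)) note("drug_lines: dose_mg must be >= 0")
    if (any(dl$cost < 0)) note("drug_lines: cost must be >= 0")
    pol <- d$drug_policies
    missing_pol <- setdiff(unique(dl$category), c(pol$category, "other"))
    if (length(missing_pol))
      note(sprintf("drug_policies: no policy for category '%s'",
                   paste(missing_pol, collapse = "', '")))
  }
  pol <- d$drug_policies
  if (nrow(pol) > 0L) {
    if (any(!pol$aggregation %in% DRUG_AGGREGATIONS))
      note("drug_policies: unknown aggregation")
    po <- pol$aggregation == "printed_override"
    if (any(po & is.na(pol$override_cost)))
      note("drug_policies: printed_override requires override_cost")
    if (any(!po & !is.na(pol$override_cost)))
      note("drug_policies: override_cost only allowed with printed_override")
  }

  sl <- d$staff_lines
  if (nrow(sl) > 0L) {
    if (any(sl$headcount < 0, na.rm = TRUE)) note("staff_lines: headcount must be >= 0")
    if (any(sl$cost < 0)) note("staff_lines: cost must be >= 0")
  }

  fc <- d$facility
  if (!is.na(fc$stay_days) && fc$stay_days < 0) note("facility: stay_days must be >= 0")
  if (!is.na(fc$or_rate_per_minute) && is.na(fc$or_minutes) && is.na(fc$or_cost))
    note("facility: or_rate_per_minute given without or_minutes")
  if (!is.na(fc$stay_rate_per_day) && is.na(fc$stay_days) && is.na(fc$stay_cost))
    note("facility: stay_rate_per_day given without stay_days")

  freqs <- vapply(d$followup_courses, function(co) co$frequency, numeric(1))
  if (length(freqs)) {
    if (any(freqs < 0 | freqs > 1))
      note("followup_courses: each frequency must lie in [0, 1]")
    if (sum(freqs) > 1 + 1e-9)
      note(sprintf(
        "followup_courses: course frequencies sum to %.4g but must sum to at most 1 (the mixture constraint)",
        sum(freqs)))
  }
  for (co in d$followup_courses) chk_items(co$items, paste0("followup[", co$name, "]"))

  ind <- d$indirect
  for (f in c("hosp_days", "convalescence_days", "hours_lost_per_day",
              "hourly_wage", "caregiver_share")) {
    if (!is.na(ind[[f]]) && ind[[f]] < 0) note(sprintf("indirect: %s must be >= 0", f))
  }
  if (!is.na(ind$caregiver_share) && ind$caregiver_share > 1)
    note("indirect: caregiver_share must be <= 1")

  r <- d$retreatment_rate
  if (!is_num_scalar(r) || r < 0 || r >= 1)
    note("retreatment_rate must lie in [0, 1)")

  if (length(bad)) {
    stop(structure(
      class = c("thyrocost_validation_error", "error", "condition"),
      list(message = paste0(
        "invalid intervention dataset '", d$name, "':\n  - ",
        paste(bad, collapse = "\n  - ")),
        call = NULL)))
  }
  invisible(d)
}

#' @export
print.intervention_dataset <- function(x, ...) {
  nfu <- length(x$followup_courses)
  cat(sprintf(
    "<intervention_dataset> %s\n  items: %d pre-hospitalization, %d drug lines, %d materials, %d staff\n  follow-up courses: %d; retreatment rate: %.3f\n",
    x$name, nrow(x$prehosp_items), nrow(x$drug_lines),
    nrow(x$material_items), nrow(x$staff_lines), nfu, x$retreatment_rate))
  invisible(x)
}
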
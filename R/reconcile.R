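#' Reconcile a dataset's printed aggregates against recomputed values
#'
#' Recomputes every aggregate that the dataset also carries in printed form
#' and reports the discrepancies. Reconciliation is diagnostic, never fatal:
#' the source tables show pervasive one-cent rounding drift (within the
#' `tol` of 0.02 EUR per aggregation step), and a handful of printed rows
#' are genuine errata that *should* fail here (the validator proving it can
#' detect them).
#'
#' @param dataset an [intervention_dataset()].
#' @param tol reconciliation tolerance in EUR (default 0.02).
#' @return a data frame with one row per check: `check`, `printed`,
#'   `computed`, `diff` (computed minus printed), `within_tol`.
#' @export
reconcile_dataset <- function(dataset, tol = RECONCILE_TOL) {
  validate_dataset(dataset)
  pr <- dataset$printed %||% list()
  ov <- dataset$phase_overrides %||% list()
  rows <- list()
  add <- function(check, printed, computed) {
    if (is.null(printed) || is.na(printed)) return(invisible())
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, printed = printed, computed = computed,
      diff = computed - printed, stringsAsFactors = FALSE)
  }

  add("prehospitalization",
      pr[["prehospitalization"]],
      phase_cost(dataset$prehosp_items, ov[["prehospitalization"]]))
  add("drugs", pr[["drugs"]], drug_cost(dataset$drug_lines, dataset$drug_policies))
  add("materials", pr[["materials"]],
      phase_cost(dataset$material_items, ov[["materials"]]))
  add("personnel", pr[["personnel"]], staff_cost(dataset$staff_lines))

  fac <- facility_cost(dataset$facility)
  fp <- dataset$facility
  if (!is.na(fp$or_cost) && !is.na(fp$or_minutes) &&
      !is.na(fp$or_rate_per_minute))
    add("operating_room_product", fp$or_cost,
        fp$or_minutes * fp$or_rate_per_minute)
  if (!is.na(fp$stay_cost) && !is.na(fp$stay_days) &&
      !is.na(fp$stay_rate_per_day))
    add("hospital_stay_product", fp$stay_cost,
        fp$stay_days * fp$stay_rate_per_day)

  # table-level materials total: item rows (not the flat override) plus the
  # facility rows the source prints inside the same table
  add("materials_table_total", pr[["materials_table_total"]],
      sum(items_cost(dataset$material_items)) + fac$or_cost + fac$stay_cost)

  for (co in dataset$followup_courses) {
    if (nrow(co$items) > 0L)
      add(paste0("course_", co$name, "_total"), co$printed_total,
          phase_cost(co$items))
  }

  # the follow-up subtotal is checked against the pure frequency-weighted
  # mixture, without any fixture residual: a residual exists precisely where
  # the printed subtotal is not explained by the mixture
  add("followup_subtotal", pr[["followup_subtotal"]],
      followup_expected_cost(dataset$followup_courses, "fidelity",
                             residual = 0))

  add("procedure_subtotal", pr[["procedure_subtotal"]], {
    r <- dataset$retreatment_rate
    comp <- c(
      drug_cost(dataset$drug_lines, dataset$drug_policies),
      phase_cost(dataset$material_items, ov[["materials"]]),
      staff_cost(dataset$staff_lines), fac$or_cost, fac$stay_cost)
    # printed phase values win where present, as in fidelity mode
    fidelity_comp <- c(pr[["drugs"]] %||% comp[1], pr[["materials"]] %||% comp[2],
                       pr[["personnel"]] %||% comp[3], comp[4], comp[5])
    sum(round_cents(fidelity_comp * (1 + r)))
  })

  add("grand_total", pr[["grand_total"]],
      intervention_total(dataset, perspective("societal"),
                         mode = "fidelity")$grand_total)

  if (!length(rows)) {
    return(data.frame(check = character(), printed = numeric(),
                      computed = numeric(), diff = numeric(),
                      within_tol = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$within_tol <- abs(out$diff) <= tol + 1e-9
  out
}

#' Reconciliation report for all bundled fixtures
#'
#' Convenience wrapper running [reconcile_dataset()] over
#' [bundled_datasets()].
#'
#' @param tol reconciliation tolerance in EUR.
#' @return a data frame with an `intervention` column prepended.
#' @export
reconcile_bundled <- function(tol = RECONCILE_TOL) {
  out <- lapply(bundled_datasets(), reconcile_dataset, tol = tol)
  do.call(rbind, Map(function(nm, df) {
    if (nrow(df)) cbind(intervention = nm, df, stringsAsFactors = FALSE)
    else df
  }, names(out), out))
}
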
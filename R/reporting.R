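# Rendering of breakdowns and comparisons. Rendering never re-aggregates:
# every number shown is taken from the cost_breakdown as computed by the
# engine, formatted to 2 decimals.

REPORT_FORMATS <- c("table-text", "csv", "json", "markdown")

#' Report configuration
#'
#' @param perspective a [perspective()] (metadata echoed into the report).
#' @param mode `"fidelity"` or `"raw"`.
#' @param currency_label currency tag shown in headers.
#' @param output_format one of `"table-text"`, `"csv"`, `"json"`,
#'   `"markdown"`.
#' @return list of class `report_config`.
#' @export
report_config <- function(perspective = thyrocost::perspective("societal"),
                          mode = "fidelity", currency_label = "EUR",
                          output_format = "table-text") {
  if (!output_format %in% REPORT_FORMATS)
    stop("report_config: output_format must be one of ",
         paste(REPORT_FORMATS, collapse = ", "))
  structure(list(perspective = perspective, mode = mode,
                 currency_label = currency_label,
                 output_format = output_format),
            class = "report_config")
}

fmt_money <- function(x, big = FALSE) {
  # dot-decimal always; thousands separators only in table-text
  formatC(round_cents(x), format = "f", digits = 2,
          big.mark = if (big) "," else "")
}

breakdown_rows <- function(breakdown) {
  pc <- breakdown$phase_costs
  rows <- list(
    c("Pre-hospitalization", pc[["prehospitalization"]]),
    c("Pharmacological therapy", pc[["drugs"]]),
    c("Materials", pc[["materials"]]),
    c("Healthcare professionals", pc[["personnel"]]))
  if (pc[["operating_room"]] != 0)
    rows <- c(rows, list(c("Operating room", pc[["operating_room"]])))
  rows <- c(rows, list(
    c("Hospital stay", pc[["hospital_stay"]]),
    c("Subtotal for the procedure", breakdown$procedure_subtotal)))
  fu <- breakdown$followup_components
  label_of <- c(standard = "Standard post-operative course",
                acute_complications = "Course with acute complications",
                chronic_complications = "Course with chronic complications",
                residual = "Unattributed follow-up residual")
  for (nm in names(fu)) {
    lbl <- if (nm %in% names(label_of)) label_of[[nm]] else nm
    rows <- c(rows, list(c(lbl, fu[[nm]])))
  }
  rows <- c(rows, list(
    c("Subtotal for follow-up", breakdown$followup_subtotal)))
  if (breakdown$perspective$include_indirect)
    rows <- c(rows, list(c("Productivity loss",
                           pc[["productivity"]])))
  rows <- c(rows, list(c("Total intervention cost", breakdown$grand_total)))
  data.frame(category = vapply(rows, `[[`, character(1), 1),
             cost = as.numeric(vapply(rows, `[[`, character(1), 2)),
             stringsAsFactors = FALSE)
}

#' Render a cost breakdown
#'
#' Emits the breakdown in the comparative-summary row order
#' (pre-hospitalization, drugs, materials, personnel, operating room,
#' hospital stay, procedure subtotal, follow-up courses and subtotal,
#' productivity loss, total).
#'
#' @param breakdown an [intervention_total()] result.
#' @param config a [report_config()].
#' @param audit append the audit trail (table-text/markdown only).
#' @return the document as a single character scalar.
#' @export
render_breakdown <- function(breakdown, config = report_config(),
                             audit = FALSE) {
  stopifnot(inherits(breakdown, "cost_breakdown"),
            inherits(config, "report_config"))
  rows <- breakdown_rows(breakdown)
  out <- switch(config$output_format,
    "table-text" = {
      hdr <- sprintf("Total cost of procedure - %s (%s, %s mode, %s)",
                     breakdown$intervention, breakdown$perspective$name,
                     breakdown$mode, config$currency_label)
      body <- sprintf("  %-36s %14s", rows$category,
                      fmt_money(rows$cost, big = TRUE))
      paste(c(hdr, strrep("-", 54), body), collapse = "\n")
    },
    csv = paste(c("category,cost",
                  sprintf("%s,%s", gsub(",", ";", rows$category),
                          fmt_money(rows$cost))), collapse = "\n"),
    json = as.character(breakdown_to_json(breakdown)),
    markdown = paste(c(
      sprintf("| Category | Cost (%s) |", config$currency_label),
      "| --- | ---: |",
      sprintf("| %s | %s |", rows$category, fmt_money(rows$cost))),
      collapse = "\n"))
  if (audit && config$output_format %in% c("table-text", "markdown")) {
    a <- breakdown$audit
    out <- paste(c(out, "", "audit trail (component, base, post-uplift, included):",
                   sprintf("  %-22s %12s %12s %s", a$component,
                           fmt_money(a$base), fmt_money(a$post_uplift),
                           ifelse(a$included, "+", "-"))),
                 collapse = "\n")
  }
  out
}

#' Render a comparison of interventions
#'
#' @param breakdowns list of [intervention_total()] results under one
#'   perspective and mode.
#' @param baseline baseline intervention name.
#' @param config a [report_config()].
#' @return the document as a character scalar.
#' @export
render_comparison <- function(breakdowns, baseline,
                              config = report_config()) {
  cmp <- compare_interventions(breakdowns, baseline)
  rows <- data.frame(
    intervention = c(cmp$baseline[1], cmp$comparator),
    total = c(cmp$baseline_total[1], cmp$comparator_total),
    absolute_saving = c(0, cmp$absolute_saving),
    relative_saving = c(0, cmp$relative_saving),
    stringsAsFactors = FALSE)
  switch(config$output_format,
    "table-text" = paste(c(
      sprintf("Cost comparison vs %s (%s, %s)", baseline,
              config$perspective$name, config$currency_label),
      strrep("-", 66),
      sprintf("  %-24s %14s %12s %8s", "intervention", "total", "saving",
              "saving%"),
      sprintf("  %-24s %14s %12s %7.1f%%", rows$intervention,
              fmt_money(rows$total, big = TRUE),
              fmt_money(rows$absolute_saving, big = TRUE),
              100 * rows$relative_saving)), collapse = "\n"),
    csv = paste(c("intervention,total,absolute_saving,relative_saving",
                  sprintf("%s,%s,%s,%.6f", rows$intervention,
                          fmt_money(rows$total),
                          fmt_money(rows$absolute_saving),
                          rows$relative_saving)), collapse = "\n"),
    json = as.character(jsonlite::toJSON(rows, dataframe = "rows",
                                         digits = NA, pretty = TRUE)),
    markdown = paste(c(
      "| Intervention | Total | Saving | Saving % |",
      "| --- | ---: | ---: | ---: |",
      sprintf("| %s | %s | %s | %.1f%% |", rows$intervention,
              fmt_money(rows$total), fmt_money(rows$absolute_saving),
              100 * rows$relative_saving)), collapse = "\n"))
}

#' Serialize a cost breakdown to JSON and back
#'
#' The JSON round-trip is lossless: [breakdown_from_json()] restores a
#' breakdown identical to the original.
#'
#' @param breakdown an [intervention_total()] result.
#' @param path optional output file.
#' @return `breakdown_to_json`: the JSON string. `breakdown_from_json`: the
#'   restored `cost_breakdown`.
#' @export
breakdown_to_json <- function(breakdown, path = NULL) {
  x <- unclass(breakdown)
  x$perspective <- unclass(x$perspective)
  # named vectors must serialize as objects, not bare arrays
  x$phase_costs <- as.list(x$phase_costs)
  x$followup_components <- as.list(x$followup_components)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns", pretty = TRUE)
  if (!is.null(path)) { writeLines(json, path); return(invisible(json)) }
  json
}

#' @rdname breakdown_to_json
#' @param json a JSON string or file path produced by
#'   [breakdown_to_json()].
#' @export
breakdown_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  x$perspective <- structure(x$perspective, class = "perspective")
  x$phase_costs <- unlist(x$phase_costs)
  x$followup_components <- if (length(x$followup_components))
    unlist(x$followup_components) else numeric()
  x$audit <- as.data.frame(x$audit, stringsAsFactors = FALSE)
  structure(x, class = "cost_breakdown")
}
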
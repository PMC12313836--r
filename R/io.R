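# Serialization of intervention datasets.
#
# Two dialects:
#  * YAML: one document whose top-level keys mirror the intervention_dataset
#    fields; item tables become lists of row maps; NA fields are omitted.
#  * CSV bundle: a directory of UTF-8, dot-decimal, headered files
#    (prehosp.csv, drugs.csv, materials.csv, staff.csv,
#    followup_<course>.csv, params.csv); scalar parameters live in
#    params.csv as dotted key/value pairs.

drop_na_fields <- function(row) row[!vapply(row, function(v)
  length(v) == 0L || (is.atomic(v) && all(is.na(v))), logical(1))]

df_to_rows <- function(df) {
  lapply(seq_len(nrow(df)), function(i) drop_na_fields(as.list(df[i, ])))
}

rows_to_df <- function(rows, template) {
  if (length(rows) == 0L) return(template)
  out <- lapply(rows, function(row) {
    full <- as.list(template[0, , drop = FALSE])
    full <- stats::setNames(
      lapply(names(template), function(nm) {
        v <- row[[nm]]
        if (is.null(v)) NA else v
      }), names(template))
    as.data.frame(full, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  for (nm in names(template)) {
    df[[nm]] <- if (is.character(template[[nm]])) as.character(df[[nm]])
                else as.numeric(df[[nm]])
  }
  df
}

dataset_to_list <- function(d) {
  list(
    name = d$name,
    prehosp_items = df_to_rows(d$prehosp_items),
    drug_lines = df_to_rows(d$drug_lines),
    drug_policies = df_to_rows(d$drug_policies),
    material_items = df_to_rows(d$material_items),
    staff_lines = df_to_rows(d$staff_lines),
    facility = drop_na_fields(unclass(d$facility)),
    followup_courses = lapply(d$followup_courses, function(co)
      drop_na_fields(list(name = co$name, frequency = co$frequency,
                          items = df_to_rows(co$items),
                          printed_total = co$printed_total))),
    indirect = drop_na_fields(unclass(d$indirect)),
    retreatment_rate = d$retreatment_rate,
    phase_overrides = d$phase_overrides,
    printed = d$printed
  )
}

dataset_from_list <- function(x, validate = TRUE) {
  fac <- do.call(facility_params, x$facility %||% list())
  ind <- do.call(indirect_params, x$indirect %||% list())
  courses <- lapply(x$followup_courses %||% list(), function(co)
    followup_course(co$name, co$frequency,
                    items = rows_to_df(co$items %||% list(), cost_items()),
                    printed_total = co$printed_total %||% NA_real_))
  intervention_dataset(
    name = x$name,
    prehosp_items = rows_to_df(x$prehosp_items %||% list(), cost_items()),
    drug_lines = rows_to_df(x$drug_lines %||% list(), drug_lines()),
    drug_policies = rows_to_df(x$drug_policies %||% list(), drug_policies()),
    material_items = rows_to_df(x$material_items %||% list(), cost_items()),
    staff_lines = rows_to_df(x$staff_lines %||% list(), staff_lines()),
    facility = fac,
    followup_courses = courses,
    indirect = ind,
    retreatment_rate = x$retreatment_rate %||% 0,
    phase_overrides = x$phase_overrides %||% list(),
    printed = x$printed %||% list(),
    validate = validate
  )
}

#' Write an intervention dataset to disk
#'
#' @param dataset a valid [intervention_dataset()].
#' @param path destination: a file for `format = "yaml"`, a directory for
#'   `format = "csv"` (created if missing).
#' @param format `"yaml"` or `"csv"` (CSV bundle directory).
#' @return `path`, invisibly.
#' @seealso [load_dataset()] — `load_dataset(write_dataset(d, p))` is the
#'   identity.
#' @export
write_dataset <- function(dataset, path, format = c("yaml", "csv")) {
  format <- match.arg(format)
  validate_dataset(dataset)
  if (format == "yaml") {
    con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                    error = function(e) stop("write_dataset: cannot open '",
                                             path, "': ", conditionMessage(e)))
    on.exit(close(con))
    writeLines(yaml::as.yaml(dataset_to_list(dataset), precision = 15L), con)
    return(invisible(path))
  }
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_dataset: cannot create directory '", path, "'")
  }
  if (file.access(path, 2L) != 0L)
    stop("write_dataset: directory '", path, "' is not writable")
  wr <- function(df, file) utils::write.csv(
    df, file.path(path, file), row.names = FALSE, fileEncoding = "UTF-8")
  wr(dataset$prehosp_items, "prehosp.csv")
  wr(merge_drug_tables(dataset$drug_lines, dataset$drug_policies),
     "drugs.csv")
  wr(dataset$material_items, "materials.csv")
  wr(dataset$staff_lines, "staff.csv")
  for (co in dataset$followup_courses)
    wr(co$items, paste0("followup_", co$name, ".csv"))

  params <- c(
    list(name = dataset$name, retreatment_rate = dataset$retreatment_rate),
    prefix_keys("facility", drop_na_fields(unclass(dataset$facility))),
    prefix_keys("indirect", drop_na_fields(unclass(dataset$indirect))),
    prefix_keys("phase_overrides", dataset$phase_overrides),
    prefix_keys("printed", dataset$printed),
    unlist(lapply(dataset$followup_courses, function(co)
      drop_na_fields(stats::setNames(
        list(co$frequency, co$printed_total),
        paste0("followup.", co$name, c(".frequency", ".printed_total"))))),
      recursive = FALSE)
  )
  pdf <- data.frame(
    key = names(params),
    value = vapply(params, function(v)
      if (is.character(v)) v else format(v, digits = 15), character(1)),
    stringsAsFactors = FALSE)
  wr(pdf, "params.csv")
  invisible(path)
}

prefix_keys <- function(prefix, x) {
  if (!length(x)) return(list())
  stats::setNames(x, paste0(prefix, ".", names(x)))
}

merge_drug_tables <- function(lines, policies) {
  if (nrow(lines) == 0L)
    return(data.frame(category = character(), drug = character(),
                      dose_mg = numeric(), cost = numeric(),
                      aggregation = character(), override_cost = numeric(),
                      stringsAsFactors = FALSE))
  i <- match(lines$category, policies$category)
  lines$aggregation <- ifelse(is.na(i),
                              ifelse(lines$category == "other",
                                     "sum_of_lines", NA_character_),
                              policies$aggregation[i])
  lines$override_cost <- ifelse(is.na(i), NA_real_, policies$override_cost[i])
  lines
}

#' Load an intervention dataset from disk
#'
#' Reads either dialect produced by [write_dataset()]. All structural
#' invariants are checked on load (a single error lists every violation);
#' reconciliation of printed aggregates is *not* enforced here — run
#' [reconcile_dataset()] for the diagnostic report.
#'
#' @param path a YAML file or a CSV-bundle directory.
#' @param format `"yaml"` or `"csv"`; by default inferred from `path`
#'   (directory implies `"csv"`).
#' @return a validated [intervention_dataset()].
#' @export
load_dataset <- function(path, format = c("auto", "yaml", "csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (dir.exists(path)) "csv" else "yaml"
  if (format == "yaml") {
    if (!file.exists(path)) stop("load_dataset: no such file: '", path, "'")
    x <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop(
                    "load_dataset: YAML parse failure in '", path, "': ",
                    conditionMessage(e), call. = FALSE))
    return(dataset_from_list(x))
  }
  if (!dir.exists(path)) stop("load_dataset: no such directory: '", path, "'")
  rd <- function(file, template, required = FALSE) {
    fp <- file.path(path, file)
    if (!file.exists(fp)) {
      if (required) stop("load_dataset: missing file '", file, "' in '",
                         path, "'")
      return(template)
    }
    df <- utils::read.csv(fp, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    missing_cols <- setdiff(names(template), names(df))
    if (length(missing_cols))
      stop("load_dataset: '", file, "' lacks column(s): ",
           paste(missing_cols, collapse = ", "))
    for (nm in names(template)) {
      df[[nm]] <- if (is.character(template[[nm]])) as.character(df[[nm]])
                  else as.numeric(df[[nm]])
    }
    df[names(template)]
  }
  params_df <- rd("params.csv",
                  data.frame(key = character(), value = character(),
                             stringsAsFactors = FALSE), required = TRUE)
  pget <- function(key) {
    v <- params_df$value[params_df$key == key]
    if (!length(v)) NULL else v
  }
  pnum <- function(key) {
    v <- pget(key)
    if (is.null(v)) NULL else as.numeric(v)
  }
  sub_params <- function(prefix) {
    sel <- startsWith(params_df$key, paste0(prefix, "."))
    keys <- substring(params_df$key[sel], nchar(prefix) + 2L)
    stats::setNames(lapply(params_df$value[sel], as.numeric), keys)
  }
  drug_tab <- rd("drugs.csv", merge_drug_tables(drug_lines(), drug_policies()))
  pol <- unique(drug_tab[!is.na(drug_tab$aggregation) &
                           drug_tab$category != "other",
                         c("category", "aggregation", "override_cost")])
  course_files <- list.files(path, pattern = "^followup_.*\\.csv$")
  courses <- lapply(course_files, function(f) {
    nm <- sub("^followup_(.*)\\.csv$", "\\1", f)
    followup_course(
      nm,
      frequency = pnum(paste0("followup.", nm, ".frequency")) %||% 0,
      items = rd(f, cost_items()),
      printed_total = pnum(paste0("followup.", nm, ".printed_total")) %||%
        NA_real_)
  })
  dataset_from_list(list(
    name = pget("name") %||% basename(path),
    prehosp_items = NULL, drug_lines = NULL,  # replaced below
    retreatment_rate = pnum("retreatment_rate") %||% 0,
    facility = sub_params("facility"),
    indirect = sub_params("indirect"),
    phase_overrides = sub_params("phase_overrides"),
    printed = sub_params("printed")
  ), validate = FALSE) -> d
  d$prehosp_items <- rd("prehosp.csv", cost_items())
  d$material_items <- rd("materials.csv", cost_items())
  d$staff_lines <- rd("staff.csv", staff_lines())
  d$drug_lines <- drug_tab[names(drug_lines())]
  d$drug_policies <- drug_policies(pol$category, pol$aggregation,
                                   pol$override_cost)
  d$followup_courses <- courses
  validate_dataset(d)
}

#' Export a validated dataset as JSON
#'
#' Numeric fields are serialized both with 2-decimal display precision
#' (`*_eur`) and as exact cents (`*_cents`), so downstream consumers can
#' avoid re-rounding.
#'
#' @param dataset an [intervention_dataset()].
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
dataset_to_json <- function(dataset, path = NULL) {
  validate_dataset(dataset)
  x <- dataset_to_list(dataset)
  decorate <- function(v) {
    if (is.numeric(v))
      list(eur = round_cents(v), cents = round(v * 100, 4))
    else if (is.list(v)) lapply(v, decorate)
    else v
  }
  json <- jsonlite::toJSON(lapply(x, decorate), auto_unbox = TRUE,
                           digits = NA, null = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Compare two datasets field-for-field
#'
#' Numeric fields compare within `tol` (serialization keeps 15 significant
#' digits, so round-trips agree far below a cent).
#'
#' @param a,b [intervention_dataset()] objects.
#' @param tol numeric tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
datasets_equal <- function(a, b, tol = 1e-8) {
  eq <- function(x, y) {
    if (is.numeric(x) && is.numeric(y))
      return(length(x) == length(y) &&
               all((is.na(x) & is.na(y)) |
                     (!is.na(x) & !is.na(y) & abs(x - y) <= tol)))
    if (is.data.frame(x) && is.data.frame(y)) {
      if (nrow(x) != nrow(y) || !identical(names(x), names(y))) return(FALSE)
      return(all(vapply(names(x), function(nm) eq(x[[nm]], y[[nm]]),
                        logical(1))))
    }
    if (is.list(x) && is.list(y)) {
      nx <- as.character(sort(names(x))); ny <- as.character(sort(names(y)))
      if (length(x) != length(y)) return(FALSE)
      if (!identical(nx, ny)) return(FALSE)
      return(all(vapply(nx, function(nm) eq(x[[nm]], y[[nm]]), logical(1))))
    }
    identical(x, y)
  }
  flds <- c("name", "prehosp_items", "drug_lines", "drug_policies",
            "material_items", "staff_lines", "retreatment_rate")
  for (f in flds) if (!eq(a[[f]], b[[f]])) return(FALSE)
  if (!eq(unclass(a$facility), unclass(b$facility))) return(FALSE)
  if (!eq(unclass(a$indirect), unclass(b$indirect))) return(FALSE)
  if (length(a$followup_courses) != length(b$followup_courses)) return(FALSE)
  an <- vapply(a$followup_courses, `[[`, character(1), "name")
  bn <- vapply(b$followup_courses, `[[`, character(1), "name")
  if (!setequal(an, bn)) return(FALSE)
  for (nm in an) {
    ca <- a$followup_courses[[match(nm, an)]]
    cb <- b$followup_courses[[match(nm, bn)]]
    if (!eq(unclass(ca)[c("frequency", "printed_total")],
            unclass(cb)[c("frequency", "printed_total")])) return(FALSE)
    if (!eq(ca$items, cb$items)) return(FALSE)
  }
  eq(a$phase_overrides, b$phase_overrides) && eq(a$printed, b$printed)
}
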
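# Uncertainty analysis over the cost model. Parameters are addressed by
# dotted paths into an intervention_dataset; item rows are selected by label
# in square brackets, e.g.
#   retreatment_rate
#   facility.stay_days
#   indirect.hourly_wage
#   material_items[Gauze].unit_cost
#   followup_courses[standard].frequency
#   followup_courses[standard].items[Neck ultrasound].weighted_cost_override
# Sensitivity runs evaluate intervention_total() in raw mode by default, so
# a change to a quantity or unit cost propagates instead of being shadowed
# by a printed aggregate.

SENS_DISTRIBUTIONS <- c("fixed", "uniform", "triangular",
                        "normal-truncated-at-zero")

#' Define a sensitivity parameter
#'
#' @param path dotted locator into an [intervention_dataset()] (see
#'   Details).
#' @param low,high range bounds (`low <= high`); used directly by sweeps and
#'   as the support of `uniform`/`triangular` draws.
#' @param distribution one of `"fixed"`, `"uniform"`, `"triangular"`,
#'   `"normal-truncated-at-zero"`.
#' @param dist_params list of distribution parameters: `value` (fixed),
#'   `mode` (triangular; defaults to the midpoint), `mean` and `sd` (normal;
#'   default midpoint and quarter-range).
#' @details A path is a dot-separated chain of fields; a table row is picked
#'   with `field[label]` (matched against the `label`, `drug` or `role`
#'   column), and a follow-up course with `followup_courses[name]`.
#' @return a list of class `param_spec`.
#' @export
param_spec <- function(path, low, high, distribution = "uniform",
                       dist_params = list()) {
  if (!distribution %in% SENS_DISTRIBUTIONS)
    stop("param_spec: unknown distribution '", distribution, "'")
  if (!is_num_scalar(low) || !is_num_scalar(high) || low > high)
    stop("param_spec: need low <= high")
  sd <- dist_params$sd
  if (!is.null(sd) && sd < 0) stop("param_spec: sd must be >= 0")
  structure(list(path = path, low = low, high = high,
                 distribution = distribution, dist_params = dist_params),
            class = "param_spec")
}

parse_path <- function(path) {
  m <- gregexpr("[^.\\[\\]]+(\\[[^\\]]+\\])?", path, perl = TRUE)[[1]]
  toks <- regmatches(path, list(m))[[1]]
  lapply(toks, function(t) {
    if (grepl("\\[", t)) {
      list(field = sub("\\[.*$", "", t),
           key = sub("^.*\\[(.*)\\]$", "\\1", t))
    } else list(field = t, key = NULL)
  })
}

row_index <- function(obj, key, path) {
  if (is.data.frame(obj)) {
    for (col in c("label", "drug", "role", "category"))
      if (col %in% names(obj)) {
        i <- match(key, obj[[col]])
        if (!is.na(i)) return(i)
      }
    stop("parameter path '", path, "': no row labelled '", key, "'")
  }
  # list of followup courses
  nms <- vapply(obj, function(co) co$name, character(1))
  i <- match(key, nms)
  if (is.na(i)) stop("parameter path '", path, "': no course '", key, "'")
  i
}

#' Read or set a dataset parameter by path
#'
#' @param dataset an [intervention_dataset()].
#' @param path dotted parameter locator (see [param_spec()]).
#' @return `get_param`: the numeric value. `set_param`: a modified copy of
#'   the dataset (the input is never mutated).
#' @export
get_param <- function(dataset, path) {
  walk_param(dataset, path, NULL)
}

#' @rdname get_param
#' @param value new numeric value.
#' @export
set_param <- function(dataset, path, value) {
  walk_param(dataset, path, value)
}

walk_param <- function(dataset, path, value) {
  toks <- parse_path(path)
  setter <- !is.null(value)
  rec <- function(obj, k) {
    tk <- toks[[k]]
    if (is.null(obj) || !(is.list(obj) || is.data.frame(obj)))
      stop("parameter path '", path, "' does not resolve")
    nxt <- obj[[tk$field]]
    if (is.null(nxt)) stop("parameter path '", path, "' does not resolve at '",
                           tk$field, "'")
    if (!is.null(tk$key)) {
      i <- row_index(nxt, tk$key, path)
      if (is.data.frame(nxt)) {
        # the remaining single token names the column
        if (k == length(toks))
          stop("parameter path '", path, "': missing column after row label")
        col <- toks[[k + 1L]]$field
        if (!col %in% names(nxt))
          stop("parameter path '", path, "': no column '", col, "'")
        if (!setter) return(nxt[[col]][i])
        nxt[[col]][i] <- value
        obj[[tk$field]] <- nxt
        return(obj)
      }
      if (k == length(toks))
        stop("parameter path '", path, "': missing field after course name")
      if (!setter) return(rec(nxt[[i]], k + 1L))
      nxt[[i]] <- rec(nxt[[i]], k + 1L)
      obj[[tk$field]] <- nxt
      return(obj)
    }
    if (k == length(toks)) {
      if (!is.numeric(nxt) || length(nxt) != 1L)
        stop("parameter path '", path, "' does not address a numeric scalar")
      if (!setter) return(nxt)
      obj[[tk$field]] <- value
      return(obj)
    }
    if (!setter) return(rec(nxt, k + 1L))
    obj[[tk$field]] <- rec(nxt, k + 1L)
    obj
  }
  out <- rec(dataset, 1L)
  if (setter) validate_dataset(out) else out
}

#' One-way sensitivity sweep
#'
#' Evaluates the grand total at evenly spaced values of one parameter,
#' holding everything else fixed. The input dataset is never mutated.
#'
#' @param dataset an [intervention_dataset()].
#' @param spec a [param_spec()].
#' @param steps number of evaluation points (>= 2) spanning
#'   `[spec$low, spec$high]`.
#' @param perspective a [perspective()].
#' @param mode costing mode; raw by default so swept quantities and prices
#'   propagate (see [intervention_total()]).
#' @return list of class `sensitivity_result`: `parameter`, `totals` (a data
#'   frame of `value`, `grand_total`, sorted by value), and `range_width`.
#' @export
one_way_sweep <- function(dataset, spec, steps = 11L,
                          perspective = thyrocost::perspective("societal"),
                          mode = "raw") {
  stopifnot(inherits(spec, "param_spec"), steps >= 2L)
  values <- seq(spec$low, spec$high, length.out = steps)
  totals <- vapply(values, function(v)
    intervention_total(set_param(dataset, spec$path, v), perspective,
                       mode)$grand_total, numeric(1))
  structure(list(
    parameter = spec$path,
    totals = data.frame(value = values, grand_total = totals),
    range_width = max(totals) - min(totals)
  ), class = "sensitivity_result")
}

#' Tornado analysis
#'
#' One low/high evaluation per parameter, ranked by the width of the induced
#' total-cost range (descending; ties broken by parameter path).
#'
#' @inheritParams one_way_sweep
#' @param specs list of [param_spec()] objects (at least one).
#' @return a data frame of class `tornado_result` with columns `parameter`,
#'   `low`, `high`, `total_low`, `total_high`, `range_width`.
#' @export
tornado <- function(dataset, specs,
                    perspective = thyrocost::perspective("societal"),
                    mode = "raw") {
  stopifnot(length(specs) >= 1L)
  rows <- lapply(specs, function(sp) {
    sw <- one_way_sweep(dataset, sp, steps = 2L, perspective, mode)
    data.frame(parameter = sp$path, low = sp$low, high = sp$high,
               total_low = sw$totals$grand_total[1],
               total_high = sw$totals$grand_total[2],
               range_width = sw$range_width, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$range_width, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado_result", "data.frame")
  out
}

draw_spec <- function(spec, n) {
  lo <- spec$low; hi <- spec$high; dp <- spec$dist_params
  switch(spec$distribution,
    fixed = rep(dp$value %||% lo, n),
    uniform = stats::runif(n, lo, hi),
    triangular = {
      mo <- dp$mode %||% ((lo + hi) / 2)
      if (mo < lo || mo > hi)
        stop("triangular mode must lie within [low, high]")
      u <- stats::runif(n)
      fc <- if (hi > lo) (mo - lo) / (hi - lo) else 0.5
      ifelse(u < fc,
             lo + sqrt(u * (hi - lo) * (mo - lo)),
             hi - sqrt((1 - u) * (hi - lo) * (hi - mo)))
    },
    `normal-truncated-at-zero` = {
      mu <- dp$mean %||% ((lo + hi) / 2)
      sd <- dp$sd %||% ((hi - lo) / 4)
      if (sd < 0) stop("normal sd must be >= 0")
      if (sd == 0) rep(max(mu, 0), n) else {
        # inverse-CDF truncation at zero
        p0 <- stats::pnorm(0, mu, sd)
        stats::qnorm(p0 + stats::runif(n) * (1 - p0), mu, sd)
      }
    },
    stop("unknown distribution '", spec$distribution, "'"))
}

#' Monte Carlo propagation of parameter uncertainty
#'
#' Draws every parameter independently from its distribution and evaluates
#' the grand total per draw. A single master seed governs all randomness;
#' each spec gets its own deterministic substream derived from the master
#' seed and its position, so appending a new spec leaves the draws of the
#' existing ones unchanged.
#'
#' @inheritParams tornado
#' @param n number of draws (>= 1).
#' @param seed integer master seed (mandatory: no implicit entropy).
#' @return list of class `monte_carlo_summary`: `n`, `seed`, `mean_total`,
#'   `sd_total`, `quantiles` (2.5/50/97.5%), and the draw-level `totals`.
#' @export
monte_carlo <- function(dataset, specs, n, seed,
                        perspective = thyrocost::perspective("societal"),
                        mode = "raw") {
  stopifnot(length(specs) >= 1L, n >= 1L, is_num_scalar(seed))
  draws <- matrix(NA_real_, nrow = n, ncol = length(specs))
  for (j in seq_along(specs)) {
    set.seed((as.integer(seed) + j * 100003L) %% 2147483647L)
    draws[, j] <- draw_spec(specs[[j]], n)
  }
  totals <- vapply(seq_len(n), function(i) {
    d <- dataset
    for (j in seq_along(specs))
      d <- set_param(d, specs[[j]]$path, draws[i, j])
    intervention_total(d, perspective, mode)$grand_total
  }, numeric(1))
  q <- stats::quantile(totals, c(0.025, 0.5, 0.975), names = FALSE)
  structure(list(
    n = n, seed = seed,
    mean_total = mean(totals),
    sd_total = if (n > 1L) stats::sd(totals) else 0,
    quantiles = stats::setNames(q, c("2.5%", "50%", "97.5%")),
    totals = totals
  ), class = "monte_carlo_summary")
}

#' @export
print.monte_carlo_summary <- function(x, ...) {
  cat(sprintf(
    "<monte_carlo_summary> n=%d seed=%d\n  mean %.2f  sd %.2f  CI95 [%.2f, %.2f]  median %.2f\n",
    x$n, x$seed, x$mean_total, x$sd_total, x$quantiles[["2.5%"]],
    x$quantiles[["97.5%"]], x$quantiles[["50%"]]))
  invisible(x)
}
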
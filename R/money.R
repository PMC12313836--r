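#' Round a monetary amount half-up to cents
#'
#' Commercial (half-up) rounding, as used in the source cost tables, rather
#' than the IEC round-half-even rule of [base::round()]. A small epsilon
#' absorbs binary floating-point representation error so that values that are
#' exactly at a half cent in decimal round up.
#'
#' @param x numeric vector of amounts in euros.
#' @param digits number of decimal places to keep (default 2, i.e. cents).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_cents(133.0272)  # 133.03
#' round_cents(9.06395)   # 9.06
#' round_cents(0.405)     # 0.41
#' @export
round_cents <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-6) / p
}

# Tolerance (EUR) for reconciling a recomputed aggregate against a printed
# one: the source tables carry pervasive one-cent rounding drift, so a
# discrepancy of up to 2 cents per aggregation step is a warning, anything
# larger is a reconciliation failure.
RECONCILE_TOL <- 0.02

`%||%` <- function(a, b) if (is.null(a)) b else a

is_num_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
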
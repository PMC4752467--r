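`%||%` <- function(a, b) if (is.null(a)) b else a

# Validation failures (bad user input / contract violations) carry their own
# condition class so callers (and the CLI) can map them to exit code 2,
# distinct from computation failures (exit code 3).
fq_stop <- function(msg, class = "fingerqc_validation_error", call. = FALSE) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

fq_compute_stop <- function(msg) fq_stop(msg, class = "fingerqc_computation_error")

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published report tables use
#' conventional half-up rounding, so all report rendering goes through this.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_area_vector <- function(x, name = "x") {
  if (!is.numeric(x)) fq_stop(sprintf("'%s' must be numeric", name))
  if (anyNA(x) || any(!is.finite(x))) {
    fq_stop(sprintf("'%s' contains missing or non-finite values", name))
  }
  if (any(x < 0)) fq_stop(sprintf("'%s' contains negative areas", name))
  invisible(x)
}
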
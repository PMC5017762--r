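#' @keywords internal
"_PACKAGE"

# Condition helpers: validation problems get a dedicated condition class so
# callers (and the CLI) can map them to a distinct exit status.

stop_validation <- function(..., call. = FALSE) {
  msg <- paste0(...)
  cond <- structure(
    class = c("cvdrecal_validation_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

stop_io <- function(..., call. = FALSE) {
  msg <- paste0(...)
  cond <- structure(
    class = c("cvdrecal_io_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

is_validation_error <- function(e) inherits(e, "cvdrecal_validation_error")

SEXES <- c("female", "male")

check_sex <- function(sex) {
  if (length(sex) != 1L || !sex %in% SEXES)
    stop_validation("sex must be one of ", paste(SEXES, collapse = ", "),
                    ", got '", paste(sex, collapse = ","), "'")
  sex
}

check_number <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop_validation(name, " must be a single finite number")
  if (x < lo || (strict_lo && x <= lo) || x > hi)
    stop_validation(name, " = ", x, " outside allowed range [",
                    lo, ", ", hi, "]", if (strict_lo) " (exclusive lower)")
  x
}
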
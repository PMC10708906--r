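#' Package-level logging
#'
#' Every pipeline stage logs its parameter values and input/output record
#' counts through this helper. Logging is off by default; enable it with
#' `options(allohex.verbose = TRUE)`.
#'
#' @param fmt `sprintf()` format string.
#' @param ... values interpolated into `fmt`.
#' @keywords internal
ax_log <- function(fmt, ...) {
  if (isTRUE(getOption("allohex.verbose", FALSE))) {
    message("[allohex] ", sprintf(fmt, ...))
  }
  invisible(NULL)
}

#' Percentage of a count, rounded for presentation
#'
#' @param n numerator count.
#' @param total denominator count, must be positive.
#' @param digits decimal places kept (default 2, the convention used for
#'   reporting genomic fractions).
#' @return `100 * n / total`, rounded to `digits`.
#' @examples
#' as_percent(219.62, 527.87)  # repetitive fraction of an assembly
#' @export
as_percent <- function(n, total, digits = 2) {
  if (!is.numeric(total) || any(total <= 0)) stop("`total` must be positive")
  round(100 * n / total, digits)
}

# stopifnot-with-message helper used by validators
ax_assert <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
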
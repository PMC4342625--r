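#' Round half away from zero
#'
#' Commercial rounding used for step deltas and percentages: .5 always moves
#' away from zero, unlike [base::round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half-away-from-zero.
#' @examples
#' round_half_up(0.5)   # 1
#' round_half_up(-0.5)  # -1
#' round_half_up(15.05, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be a single non-missing number", name)
  }
  if (x < min) stopf("`%s` must be >= %s", name, format(min))
  invisible(x)
}
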
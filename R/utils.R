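#' Round half away from zero
#'
#' Rounding used at the reporting layer for percentages (e.g. 82.15 -> 82.2,
#' not banker's rounding). Base \code{round()} rounds half to even, which does
#' not reproduce conventional printed tables.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(6.25, 6.35), 1)  # 6.3 6.4
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# stop() with sprintf formatting, no call in message
bc_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

bc_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# checks x is a single finite number in [lo, hi]
check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    bc_stop("'%s' must be a single finite number in [%s, %s]", name, lo, hi)
  invisible(x)
}
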
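#' @keywords internal
"_PACKAGE"

INT32_MAX <- 2147483647
INT32_MIN <- -2147483648

#' Ceiling of log base 2
#'
#' Exact integer computation of `ceiling(log2(x))` for positive integers,
#' avoiding floating-point log near powers of two.
#'
#' @param x Positive integer (vectorized).
#' @return Integer vector, `ceiling(log2(x))`.
#' @examples
#' ceil_log2(c(1, 2, 3, 8, 15154))
#' @export
ceil_log2 <- function(x) {
  if (any(x < 1)) stop("ceil_log2 requires x >= 1")
  vapply(x, function(xi) {
    p <- 0L
    v <- 1
    while (v < xi) {
      v <- v * 2
      p <- p + 1L
    }
    p
  }, integer(1))
}

# round half away from zero; R's round() is banker's rounding
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# guard: values must be exactly representable as 32-bit signed integers
check_int32 <- function(x, what = "value") {
  if (any(x > INT32_MAX | x < INT32_MIN)) {
    stop(sprintf("32-bit signed overflow in %s (max |value| = %.0f)",
                 what, max(abs(x))))
  }
  invisible(x)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}
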
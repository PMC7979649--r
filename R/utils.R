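#' Wrap phase values into the principal interval
#'
#' Maps angles (radians) into `(-pi, pi]`, the storage convention for all
#' phase maps in this package.
#'
#' @param x Numeric vector, matrix or array of angles in radians.
#' @return Object of the same shape with every value in `(-pi, pi]`.
#' @examples
#' wrap_phase(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi
  w
}

# Evaluate an expression under a fixed RNG seed without disturbing the
# caller's RNG state; seed = NULL runs the expression as-is.
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
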
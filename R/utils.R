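#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for all displayed percentages,
#' hours and days. `round()` in R rounds half to even, which disagrees with
#' the reporting convention on exact .5 values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))   # 1 2 3, unlike round()
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by one ulp so values that are .5 only up to binary representation
  # error (e.g. 100 * 9839/24312) still round up
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# Derive reproducible 32-bit sub-seeds from a master seed so that each
# stochastic stage of a run can be replayed in isolation.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max,
                   sample.int(.Machine$integer.max - 1L, n))
}
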
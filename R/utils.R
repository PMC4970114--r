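#' @importFrom stats rnorm runif sd predict
#' @importFrom utils head tail
NULL

#' Round half away from zero
#'
#' Fixed-point rounding with halves going up (97.665 -> 97.67), the convention
#' used when reporting percentages in the result tables. Base `round()` uses
#' round-half-to-even, which would report e.g. 0.125 as 0.12.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Activity class coding
#'
#' The four activity classes and their integer codes: eating while sitting
#' (1), sedentary (2, combining quiet sitting and talking), eating while
#' walking (3), and walking (4).
#'
#' @return named integer vector mapping class name to code.
#' @export
class_levels <- function() {
  c(eat_sit = 1L, sedentary = 2L, eat_walk = 3L, walk = 4L)
}

class_names <- function() names(class_levels())

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}
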
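#' @importFrom stats runif rnorm qnorm setNames
#' @importFrom utils head tail write.csv
NULL

SPHERE_FIELDS <- c("x", "y", "z", "size", "hue", "sat", "val")
SIZE_FLOOR <- 0.01
FORMAT_VERSION <- "1.0"

#' Wrap a hue value onto the chromatic circle
#'
#' Hue lives on a circle of period 1 with red at both ends, so any real
#' number maps into the canonical interval \code{[0, 1)}.
#'
#' @param h numeric vector of hue values (any real).
#' @return numeric vector in \code{[0, 1)}.
#' @examples
#' wrap_hue(c(1.0, 1.25, -0.25))
#' @export
wrap_hue <- function(h) h %% 1

#' Signed circular hue difference
#'
#' Smallest signed difference \code{a - b} on the hue circle, in
#' \code{(-0.5, 0.5]}. Ties at the antipode resolve to +0.5 (increasing hue).
#'
#' @param a,b numeric vectors of hues.
#' @return signed difference in \code{(-0.5, 0.5]}.
#' @export
hue_diff <- function(a, b) {
  d <- (a - b) %% 1
  ifelse(d > 0.5, d - 1, d)
}

#' Circular hue distance
#'
#' @param a,b numeric vectors of hues.
#' @return nonnegative distance in \code{[0, 0.5]}.
#' @export
hue_dist <- function(a, b) abs(hue_diff(a, b))

# Derive per-member child seeds from a master seed.  Documented fan-out:
# the master seed initialises R's RNG once and n integer seeds are drawn,
# so member i is reproducible and members are mutually independent.
fanout_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

stop_arg <- function(...) stop(..., call. = FALSE)
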
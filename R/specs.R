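#' Uniform deviation range
#'
#' Specifies the magnitude band for uniform-mode perturbation: a deviation
#' magnitude is drawn from \code{U[lo, hi]} and applied with a fair random
#' sign, so derived values land symmetrically on either side of the base.
#'
#' @param lo,hi nonnegative magnitudes with \code{lo <= hi}; \code{hi}
#'   defaults to \code{lo} (a fixed magnitude).
#' @return an object of class \code{sc_delta}.
#' @export
delta_range <- function(lo, hi = lo) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1 || length(hi) != 1)
    stop_arg("`lo` and `hi` must be single numbers")
  if (lo < 0 || hi < 0) stop_arg("deviation magnitudes must be nonnegative")
  if (lo > hi) stop_arg("`lo` must not exceed `hi`")
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi)),
            class = c("sc_delta", "sc_dev"))
}

#' Gaussian deviation specification
#'
#' Specifies Gaussian-mode perturbation: the derived value is drawn from
#' \code{Normal(base, sigma)}.  For position shifts the distance is the
#' half-normal \code{|Normal(0, sigma)|} (distances are nonnegative).
#'
#' @param sigma nonnegative standard deviation.
#' @return an object of class \code{sc_gauss}.
#' @export
gauss_spec <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    stop_arg("`sigma` must be a single nonnegative number")
  structure(list(sigma = as.numeric(sigma)), class = c("sc_gauss", "sc_dev"))
}

is_delta <- function(x) inherits(x, "sc_delta")
is_gauss <- function(x) inherits(x, "sc_gauss")

#' @export
print.sc_delta <- function(x, ...) {
  cat(sprintf("<delta_range> [%g, %g]\n", x$lo, x$hi)); invisible(x)
}

#' @export
print.sc_gauss <- function(x, ...) {
  cat(sprintf("<gauss_spec> sigma = %g\n", x$sigma)); invisible(x)
}

#' Per-parameter category perturbation specification
#'
#' Bundles the deviation specifications used to derive category members from
#' a base stimulus.  \code{position_shift} controls the polar XZ shift
#' distance (the shift angle is always uniform on \code{[0, 2*pi)});
#' \code{y_dev} perturbs depth independently, like the scalar parameters.
#' All sub-specifications must match \code{mode}: \code{delta_range} for
#' \code{"uniform"}, \code{gauss_spec} for \code{"gauss"}.
#'
#' @param mode \code{"uniform"} or \code{"gauss"}.
#' @param position_shift,y_dev,size_dev,hue_dev,sat_dev,val_dev deviation
#'   specs (\code{\link{delta_range}} or \code{\link{gauss_spec}}); defaults
#'   are zero deviations in the chosen mode.
#' @return an object of class \code{sc_category_spec}.
#' @export
category_spec <- function(mode = c("uniform", "gauss"),
                          position_shift = NULL, y_dev = NULL,
                          size_dev = NULL, hue_dev = NULL,
                          sat_dev = NULL, val_dev = NULL) {
  mode <- match.arg(mode)
  zero <- if (mode == "uniform") delta_range(0, 0) else gauss_spec(0)
  devs <- list(position_shift = position_shift, y_dev = y_dev,
               size_dev = size_dev, hue_dev = hue_dev,
               sat_dev = sat_dev, val_dev = val_dev)
  devs <- lapply(devs, function(d) if (is.null(d)) zero else d)
  ok <- if (mode == "uniform") vapply(devs, is_delta, logical(1))
        else vapply(devs, is_gauss, logical(1))
  if (!all(ok))
    stop_arg("sub-specs not matching mode '", mode, "': ",
             paste(names(devs)[!ok], collapse = ", "))
  structure(c(list(mode = mode), devs), class = "sc_category_spec")
}

#' @export
print.sc_category_spec <- function(x, ...) {
  cat(sprintf("<category_spec> mode = %s\n", x$mode))
  for (nm in c("position_shift", "y_dev", "size_dev", "hue_dev",
               "sat_dev", "val_dev")) {
    d <- x[[nm]]
    cat(sprintf("  %-14s %s\n", nm,
                if (is_delta(d)) sprintf("[%g, %g]", d$lo, d$hi)
                else sprintf("sigma %g", d$sigma)))
  }
  invisible(x)
}

#' Construct a category object
#'
#' A category is a base stimulus (the prototype), the members derived from
#' it, and the specification they were derived under.  Every member must
#' share the base's sphere count.
#'
#' @param base an \code{sc_stimulus}.
#' @param members list of \code{sc_stimulus}.
#' @param spec the \code{\link{category_spec}} used for derivation.
#' @return an object of class \code{sc_category}.
#' @export
new_category <- function(base, members, spec) {
  if (!inherits(base, "sc_stimulus")) stop_arg("`base` must be an sc_stimulus")
  if (!length(members)) stop_arg("a category needs at least one member")
  counts <- vapply(members, n_spheres, integer(1))
  if (any(counts != n_spheres(base)))
    stop_arg("all members must have the base's sphere count (",
             n_spheres(base), ")")
  structure(list(base = base, members = members, spec = spec),
            class = "sc_category")
}

#' @export
print.sc_category <- function(x, ...) {
  cat(sprintf("<sc_category> %d members of %d spheres, mode = %s\n",
              length(x$members), n_spheres(x$base), x$spec$mode))
  invisible(x)
}
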
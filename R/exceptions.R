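#' Per-parameter limits of a category
#'
#' Computes, for each sphere index and each parameter, the minimum and
#' maximum observed across the category's members (the base is not included
#' unless it is a member).  These extremes are the starting point for
#' exception generation.  Hue is handled on the circle: member hues are
#' unwrapped around the base stimulus' hue (smallest signed circular
#' difference) before taking min/max, so limits are meaningful even when the
#' category straddles red.
#'
#' With \code{per_sphere = FALSE} the limits are pooled across spheres
#' (every sphere gets the category-wide extreme per parameter).
#'
#' @param cat an \code{sc_category} with at least one member.
#' @param per_sphere compute limits per sphere index (default) or pooled.
#' @return an object of class \code{sc_limits}: matrices \code{lower} and
#'   \code{upper} (spheres x parameters; hue columns are on the unwrapped
#'   scale) plus the base hues used as unwrapping reference.
#' @export
category_limits <- function(cat, per_sphere = TRUE) {
  if (!inherits(cat, "sc_category")) stop_arg("`cat` must be an sc_category")
  if (length(cat$members) < 1) stop_arg("category has no members")
  ns <- n_spheres(cat$base)
  ref_hue <- cat$base$spheres$hue
  # members x spheres value array per field; hue unwrapped around base hue
  vals <- lapply(setNames(SPHERE_FIELDS, SPHERE_FIELDS), function(f) {
    m <- t(vapply(cat$members, function(s) {
      v <- s$spheres[[f]]
      if (f == "hue") v <- ref_hue + hue_diff(v, ref_hue)
      v
    }, numeric(ns)))
    if (ns == 1) m <- matrix(m, ncol = 1)
    m
  })
  lower <- vapply(vals, function(m) apply(m, 2, min), numeric(ns))
  upper <- vapply(vals, function(m) apply(m, 2, max), numeric(ns))
  if (ns == 1) {
    lower <- matrix(lower, nrow = 1, dimnames = list(NULL, SPHERE_FIELDS))
    upper <- matrix(upper, nrow = 1, dimnames = list(NULL, SPHERE_FIELDS))
  }
  if (!per_sphere) {
    lower <- matrix(rep(apply(lower, 2, min), each = ns), nrow = ns,
                    dimnames = list(NULL, SPHERE_FIELDS))
    upper <- matrix(rep(apply(upper, 2, max), each = ns), nrow = ns,
                    dimnames = list(NULL, SPHERE_FIELDS))
  }
  structure(list(lower = lower, upper = upper, ref_hue = ref_hue,
                 per_sphere = per_sphere),
            class = "sc_limits")
}

#' @export
print.sc_limits <- function(x, ...) {
  cat(sprintf("<sc_limits> %d spheres, %s\n", nrow(x$lower),
              if (x$per_sphere) "per-sphere" else "pooled"))
  invisible(x)
}

default_exception_dev <- function() {
  setNames(lapply(SPHERE_FIELDS, function(f) delta_range(0, 0)),
           SPHERE_FIELDS)
}

#' Generate category exceptions from a category's parameter limits
#'
#' Exceptions sit outside a category's parametric extent.  For every sphere
#' and every parameter, a side is chosen (above the upper limit or below the
#' lower, fair coin per draw), a deviation magnitude is drawn from
#' \code{U[lo, hi]} and the exception value is \code{upper + magnitude} or
#' \code{lower - magnitude}.  With both bounds set to 0 the exception sits
#' exactly on the category extremes — still typically far from the base
#' stimulus.  Sizes are floored at 0.01, sat/val clamped to \code{[0, 1]};
#' hue deviations act on the unwrapped scale (see
#' \code{\link{category_limits}}) and are re-wrapped onto the circle.
#'
#' @param cat an \code{sc_category}.
#' @param dev named list of \code{\link{delta_range}} per parameter
#'   (\code{x, y, z, size, hue, sat, val}); omitted parameters default to
#'   \code{delta_range(0, 0)}.
#' @param m number of exception stimuli (at least 1).
#' @param seed master integer seed.
#' @param per_sphere passed to \code{\link{category_limits}}.
#' @return list of \code{m} \code{sc_stimulus} objects with the category's
#'   sphere count.
#' @export
exceptions_from_limits <- function(cat, dev = list(), m, seed,
                                   per_sphere = TRUE) {
  if (!is_count(m)) stop_arg("`m` must be a positive integer")
  full <- default_exception_dev()
  bad <- setdiff(names(dev), SPHERE_FIELDS)
  if (length(bad)) stop_arg("unknown parameter(s) in `dev`: ",
                            paste(bad, collapse = ", "))
  for (nm in names(dev)) {
    if (!is_delta(dev[[nm]]))
      stop_arg("`dev$", nm, "` must be a delta_range")
    full[[nm]] <- dev[[nm]]
  }
  lim <- category_limits(cat, per_sphere = per_sphere)
  ns <- n_spheres(cat$base)
  seeds <- fanout_seeds(seed, m)
  lapply(seq_len(m), function(i) {
    sp <- withr::with_seed(seeds[i], {
      out <- cat$base$spheres
      for (f in SPHERE_FIELDS) {
        d <- full[[f]]
        mag <- runif(ns, d$lo, d$hi)
        up <- sample(c(TRUE, FALSE), ns, replace = TRUE)
        v <- ifelse(up, lim$upper[, f] + mag, lim$lower[, f] - mag)
        out[[f]] <- v
      }
      out
    })
    cl <- clamp_sphere_fields(sp)
    lineage <- "exception:limits"
    if (cl$n_clamped > 0)
      lineage <- paste0(lineage, ";clamped=", cl$n_clamped)
    new_stimulus(cl$spheres,
                 label = sprintf("%s/exception%02d", cat$base$label, i),
                 seed = seeds[i], lineage = lineage)
  })
}

#' Generate category exceptions from a dedicated exception base stimulus
#'
#' The alternative construction: instead of pushing past a category's
#' limits, the user designs an exception base stimulus and derives
#' exceptions from it with uniform min/max ranges per parameter — the same
#' machinery as uniform-mode category generation.  Because the exception
#' base is free-standing, its sphere count may differ from the category's.
#'
#' @param exception_base an \code{sc_stimulus}.
#' @param spec a uniform-mode \code{\link{category_spec}} giving the ranges.
#' @param m number of exceptions (at least 1).
#' @param seed master integer seed.
#' @return list of \code{m} \code{sc_stimulus} objects with
#'   \code{exception_base}'s sphere count.
#' @export
exceptions_from_base <- function(exception_base, spec, m, seed) {
  if (!inherits(exception_base, "sc_stimulus"))
    stop_arg("`exception_base` must be an sc_stimulus")
  if (!inherits(spec, "sc_category_spec") || spec$mode != "uniform")
    stop_arg("`spec` must be a uniform-mode category_spec")
  if (!is_count(m)) stop_arg("`m` must be a positive integer")
  seeds <- fanout_seeds(seed, m)
  lapply(seq_len(m), function(i) {
    s <- derive_member(exception_base, spec, seeds[i])
    s$label <- sprintf("%s/exception%02d", exception_base$label, i)
    s$lineage <- sub("^derived:uniform", "exception:base", s$lineage)
    s
  })
}
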
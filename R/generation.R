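#' Sampling ranges for random base stimuli
#'
#' Base stimuli are sampled uniformly and independently per field within
#' these intervals.  Defaults: positions in \code{[-1, 1]} per axis, size in
#' \code{[0.05, 0.25]}, saturation and value in \code{[0.6, 1]} (keeps
#' spheres visibly colored — low saturation gives pale spheres, low value
#' near-black ones).  Hue is always uniform on the full circle \code{[0, 1)}.
#'
#' @param x,y,z length-2 position intervals (scene units).
#' @param size length-2 radius interval; lower end must be at least 0.01.
#' @param sat,val length-2 intervals within \code{[0, 1]}.
#' @return an object of class \code{sc_base_ranges}.
#' @export
base_ranges <- function(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1),
                        size = c(0.05, 0.25), sat = c(0.6, 1),
                        val = c(0.6, 1)) {
  chk <- function(r, nm, lo = -Inf, hi = Inf) {
    if (!is.numeric(r) || length(r) != 2 || any(!is.finite(r)))
      stop_arg("`", nm, "` must be a finite length-2 interval")
    if (r[1] > r[2]) stop_arg("`", nm, "`: lower bound exceeds upper")
    if (r[1] < lo || r[2] > hi)
      stop_arg("`", nm, "` must lie within [", lo, ", ", hi, "]")
    as.numeric(r)
  }
  structure(list(x = chk(x, "x"), y = chk(y, "y"), z = chk(z, "z"),
                 size = chk(size, "size", lo = SIZE_FLOOR),
                 sat = chk(sat, "sat", 0, 1), val = chk(val, "val", 0, 1)),
            class = "sc_base_ranges")
}

#' Generate a random base stimulus
#'
#' Samples \code{n_spheres} spheres with independent uniform draws per field
#' (see \code{\link{base_ranges}}).  The sphere count is the defining input;
#' everything else is random but fully determined by \code{seed}.
#'
#' @param n_spheres number of spheres (at least 1).
#' @param seed integer seed; identical seeds give identical stimuli.
#' @param ranges a \code{\link{base_ranges}} object.
#' @param label free-text label.
#' @return an \code{sc_stimulus} with \code{lineage = "base"}.
#' @examples
#' b <- make_base(8, seed = 42)
#' n_spheres(b)
#' @export
make_base <- function(n_spheres, seed, ranges = base_ranges(),
                      label = "base") {
  if (!is_count(n_spheres)) stop_arg("`n_spheres` must be a positive integer")
  if (!inherits(ranges, "sc_base_ranges"))
    stop_arg("`ranges` must come from base_ranges()")
  n <- as.integer(n_spheres)
  sp <- withr::with_seed(as.integer(seed), data.frame(
    x = runif(n, ranges$x[1], ranges$x[2]),
    y = runif(n, ranges$y[1], ranges$y[2]),
    z = runif(n, ranges$z[1], ranges$z[2]),
    size = runif(n, ranges$size[1], ranges$size[2]),
    hue = runif(n, 0, 1),
    sat = runif(n, ranges$sat[1], ranges$sat[2]),
    val = runif(n, ranges$val[1], ranges$val[2])))
  new_stimulus(sp, label = label, seed = seed, lineage = "base")
}

#' Perturb scalar parameter values
#'
#' The scalar perturbation primitive used for depth (y), size, hue,
#' saturation and value.  Uniform mode adds or subtracts (fair random sign) a
#' magnitude drawn from \code{U[lo, hi]}; Gaussian mode draws from
#' \code{Normal(base, sigma)}.  With \code{clamp = TRUE} the result is then
#' forced legal for its kind: sizes floored at 0.01, unit-interval parameters
#' clamped to \code{[0, 1]}, hue wrapped modulo 1.  \code{clamp = FALSE}
#' returns the raw draws (useful for auditing the sampling distribution).
#'
#' Uses the current RNG state; seed at the call site for reproducibility.
#'
#' @param base numeric vector of base values.
#' @param dev a \code{\link{delta_range}} or \code{\link{gauss_spec}}.
#' @param kind \code{"linear"} (unbounded, e.g. y), \code{"size"},
#'   \code{"unit"} (sat/val) or \code{"circular"} (hue).
#' @param clamp apply the post-sampling bounds?
#' @return numeric vector of perturbed values, same length as \code{base}.
#' @export
perturb_scalar <- function(base, dev,
                           kind = c("linear", "size", "unit", "circular"),
                           clamp = TRUE) {
  kind <- match.arg(kind)
  if (!inherits(dev, "sc_dev"))
    stop_arg("`dev` must be a delta_range or gauss_spec")
  n <- length(base)
  raw <- if (is_delta(dev)) {
    m <- runif(n, dev$lo, dev$hi)
    s <- sample(c(-1, 1), n, replace = TRUE)
    base + s * m
  } else {
    rnorm(n, mean = base, sd = dev$sigma)
  }
  if (!clamp) return(raw)
  switch(kind,
         linear = raw,
         size = pmax(raw, SIZE_FLOOR),
         unit = pmin(pmax(raw, 0), 1),
         circular = wrap_hue(raw))
}

#' Shift XZ positions in polar coordinates
#'
#' Each point is moved by a distance \code{d} in a random direction: the
#' angle is uniform on \code{[0, 2*pi)} and \code{d} comes from the deviation
#' spec (uniform: \code{U[lo, hi]}; Gaussian: half-normal
#' \code{|Normal(0, sigma)|}, since distances are nonnegative).  The polar
#' displacement is converted back to Cartesian offsets, so the Euclidean XZ
#' displacement equals the drawn distance exactly.  Depth (y) is never
#' touched here — it is perturbed independently via
#' \code{\link{perturb_scalar}}.
#'
#' Uses the current RNG state; seed at the call site for reproducibility.
#'
#' @param x,z numeric vectors of coordinates (same length).
#' @param dist_dev a \code{\link{delta_range}} or \code{\link{gauss_spec}}
#'   for the shift distance.
#' @return a list with components \code{x}, \code{z} (shifted coordinates),
#'   \code{theta} and \code{dist} (the draws).
#' @export
shift_position <- function(x, z, dist_dev) {
  if (!inherits(dist_dev, "sc_dev"))
    stop_arg("`dist_dev` must be a delta_range or gauss_spec")
  n <- length(x)
  if (length(z) != n) stop_arg("`x` and `z` must have the same length")
  theta <- runif(n, 0, 2 * pi)
  d <- if (is_delta(dist_dev)) runif(n, dist_dev$lo, dist_dev$hi)
       else abs(rnorm(n, 0, dist_dev$sigma))
  list(x = x + d * cos(theta), z = z + d * sin(theta),
       theta = theta, dist = d)
}

#' Derive a category member from a base stimulus
#'
#' Applies the polar XZ shift and independent scalar perturbations (y, size,
#' hue, sat, val) to every sphere of \code{base}, per sphere and per
#' parameter independently.  The sphere count is preserved; sizes are floored
#' at 0.01, sat/val clamped to \code{[0, 1]} and hue wrapped.  Lineage
#' records the mode and, if any clamp fired, how many values were clamped.
#'
#' @param base an \code{sc_stimulus}.
#' @param spec a \code{\link{category_spec}}.
#' @param seed integer seed.
#' @param clamp apply bounds (default); \code{FALSE} keeps raw draws, for
#'   distribution audits only.
#' @return an \code{sc_stimulus}.
#' @export
derive_member <- function(base, spec, seed, clamp = TRUE) {
  if (!inherits(base, "sc_stimulus")) stop_arg("`base` must be an sc_stimulus")
  if (!inherits(spec, "sc_category_spec"))
    stop_arg("`spec` must come from category_spec()")
  raw <- withr::with_seed(as.integer(seed), {
    r <- base$spheres
    pos <- shift_position(r$x, r$z, spec$position_shift)
    r$x <- pos$x
    r$z <- pos$z
    r$y <- perturb_scalar(r$y, spec$y_dev, "linear", clamp = FALSE)
    r$size <- perturb_scalar(r$size, spec$size_dev, "size", clamp = FALSE)
    r$hue <- perturb_scalar(r$hue, spec$hue_dev, "circular", clamp = FALSE)
    r$sat <- perturb_scalar(r$sat, spec$sat_dev, "unit", clamp = FALSE)
    r$val <- perturb_scalar(r$val, spec$val_dev, "unit", clamp = FALSE)
    r
  })
  lineage <- paste0("derived:", spec$mode)
  if (!clamp) {
    # test hook: bypass constructor wrapping too, so raw bands are observable
    return(structure(
      list(spheres = raw, label = paste0(base$label, "/member"),
           seed = as.integer(seed), lineage = paste0(lineage, ";unclamped")),
      class = "sc_stimulus"))
  }
  cl <- clamp_sphere_fields(raw)
  if (cl$n_clamped > 0)
    lineage <- paste0(lineage, ";clamped=", cl$n_clamped)
  new_stimulus(cl$spheres, label = paste0(base$label, "/member"),
               seed = seed, lineage = lineage)
}

#' Generate a full category from a base stimulus
#'
#' Derives \code{n_members} member stimuli from \code{base} under
#' \code{spec}.  Member seeds are fanned out deterministically from the
#' master seed, so the whole category is reproducible while members stay
#' mutually independent.  All members share the base's sphere count.
#'
#' @param base an \code{sc_stimulus}.
#' @param spec a \code{\link{category_spec}}.
#' @param n_members number of members to derive (at least 1).
#' @param seed master integer seed.
#' @return an \code{sc_category}.
#' @examples
#' b <- make_base(6, seed = 7)
#' spec <- category_spec("uniform", size_dev = delta_range(0.02, 0.05))
#' cat6 <- generate_category(b, spec, n_members = 10, seed = 11)
#' length(cat6$members)
#' @export
generate_category <- function(base, spec, n_members, seed) {
  if (!is_count(n_members)) stop_arg("`n_members` must be a positive integer")
  seeds <- fanout_seeds(seed, n_members)
  members <- lapply(seq_len(n_members), function(i) {
    m <- derive_member(base, spec, seeds[i])
    m$label <- sprintf("%s/member%03d", base$label, i)
    m
  })
  new_category(base, members, spec)
}

#' Preview exemplars at the extremes of a category specification
#'
#' Builds two illustrative stimuli showing how far category members can
#' stray from the base.  Uniform mode places them at the maximal deviation
#' magnitude \code{hi} (one subtracting, one adding).  Gaussian mode places
#' them at the two-sided tail quantiles of \code{Normal(base, sigma)}: with
#' the default \code{tail_mass = 0.05}, at the 2.5th and 97.5th percentiles.
#' (If the stated "5 percent tails" is read as 5 percent per tail, pass
#' \code{tail_mass = 0.10}.)  Positions are shifted by the extreme distance
#' along fixed opposite directions (-x and +x) so the preview is
#' deterministic.
#'
#' @param base an \code{sc_stimulus}.
#' @param spec a \code{\link{category_spec}}.
#' @param tail_mass total two-sided tail probability (Gaussian mode).
#' @return a list of two \code{sc_stimulus} objects, \code{low} and
#'   \code{high}.
#' @export
preview_exemplars <- function(base, spec, tail_mass = 0.05) {
  if (!inherits(spec, "sc_category_spec"))
    stop_arg("`spec` must come from category_spec()")
  if (tail_mass <= 0 || tail_mass >= 1)
    stop_arg("`tail_mass` must be in (0, 1)")
  extreme <- function(dev) {
    if (is_delta(dev)) dev$hi else qnorm(1 - tail_mass / 2) * dev$sigma
  }
  one <- function(sign, theta, tag) {
    sp <- base$spheres
    d <- extreme(spec$position_shift)
    sp$x <- sp$x + d * cos(theta)
    sp$z <- sp$z + d * sin(theta)
    sp$y <- sp$y + sign * extreme(spec$y_dev)
    sp$size <- pmax(sp$size + sign * extreme(spec$size_dev), SIZE_FLOOR)
    sp$hue <- wrap_hue(sp$hue + sign * extreme(spec$hue_dev))
    sp$sat <- pmin(pmax(sp$sat + sign * extreme(spec$sat_dev), 0), 1)
    sp$val <- pmin(pmax(sp$val + sign * extreme(spec$val_dev), 0), 1)
    new_stimulus(sp, label = paste0(base$label, "/preview-", tag),
                 seed = base$seed, lineage = paste0("preview:", spec$mode))
  }
  list(low = one(-1, pi, "low"), high = one(+1, 0, "high"))
}
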
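#' Parametric deviation of a stimulus from a reference
#'
#' Quantifies how far each sphere of \code{s} has strayed from the
#' corresponding sphere of \code{ref} (pairing by index): Euclidean position
#' distance in the display plane (\code{xz_distance}) and in full 3D
#' (\code{xyz_distance}), absolute size difference, circular hue distance
#' \code{min(|dh|, 1 - |dh|)}, and absolute saturation/value differences.
#' This is deliberately a table of separate parametric deviations, not one
#' scalar similarity: numeric deviations need not track perceived similarity,
#' so downstream models (e.g. a GLM on performance data) should see the
#' parameters individually.
#'
#' @param s,ref \code{sc_stimulus} objects with equal sphere counts.
#' @return an object of class \code{sc_deviation}: \code{per_sphere} (a
#'   data.frame, one row per sphere) plus \code{mean} and \code{max}
#'   aggregate vectors over spheres.
#' @examples
#' b <- make_base(5, seed = 3)
#' d <- stimulus_deviation(b, b)
#' all(d$per_sphere == 0)
#' @export
stimulus_deviation <- function(s, ref) {
  if (!inherits(s, "sc_stimulus") || !inherits(ref, "sc_stimulus"))
    stop_arg("`s` and `ref` must be sc_stimulus objects")
  if (n_spheres(s) != n_spheres(ref))
    stop_arg("sphere counts differ (", n_spheres(s), " vs ",
             n_spheres(ref), "); deviation pairs spheres by index")
  a <- s$spheres
  b <- ref$spheres
  per <- data.frame(
    xz_distance = sqrt((a$x - b$x)^2 + (a$z - b$z)^2),
    xyz_distance = sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2),
    size_abs_dev = abs(a$size - b$size),
    hue_circ_dev = hue_dist(a$hue, b$hue),
    sat_abs_dev = abs(a$sat - b$sat),
    val_abs_dev = abs(a$val - b$val))
  structure(list(per_sphere = per,
                 mean = vapply(per, mean, numeric(1)),
                 max = vapply(per, max, numeric(1))),
            class = "sc_deviation")
}

#' @export
print.sc_deviation <- function(x, ...) {
  cat("<sc_deviation> aggregates over", nrow(x$per_sphere), "spheres:\n")
  print(rbind(mean = x$mean, max = x$max), digits = 4)
  invisible(x)
}

# scalar ordering key used by the training schedulers; ad hoc sum of the
# mean aggregates (documented as an ordering device, not a similarity claim)
deviation_key <- function(s, ref) sum(stimulus_deviation(s, ref)$mean)

#' Within-category deviation table
#'
#' One row per member with the mean and max per-parameter deviations of that
#' member from the category base — the "basic, mathematical similarity"
#' summary of a category.  Write it with \code{write.csv} for downstream
#' analysis.
#'
#' @param cat an \code{sc_category}.
#' @return a data.frame with columns \code{member}, \code{label},
#'   \code{mean_*} and \code{max_*} for each deviation measure.
#' @export
category_deviation_table <- function(cat) {
  if (!inherits(cat, "sc_category")) stop_arg("`cat` must be an sc_category")
  rows <- lapply(seq_along(cat$members), function(i) {
    d <- stimulus_deviation(cat$members[[i]], cat$base)
    c(list(member = i, label = cat$members[[i]]$label),
      as.list(setNames(d$mean, paste0("mean_", names(d$mean)))),
      as.list(setNames(d$max, paste0("max_", names(d$max)))))
  })
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}
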
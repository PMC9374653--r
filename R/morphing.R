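#' Morph one stimulus into another through a parameter-space continuum
#'
#' Builds an ordered series of stimuli from \code{parent1} to \code{parent2}
#' with \code{k} in-between steps.  Sphere \code{i} of parent1 morphs into
#' sphere \code{i} of parent2 (pairing follows the stored sphere order), so
#' both parents must have the same sphere count.  Every scalar parameter is
#' interpolated linearly, \code{p = p1 + j/(k+1) * (p2 - p1)} at step
#' \code{j}, giving equal physical spacing between adjacent steps — the
#' property a categorical-perception continuum needs.  Hue travels along the
#' shortest circular arc (exact antipodes break ties toward increasing hue);
#' interpolated sizes are floored at 0.01.
#'
#' @param parent1,parent2 \code{sc_stimulus} objects with equal sphere
#'   counts.
#' @param k number of in-between stimuli (nonnegative integer).
#' @return an object of class \code{sc_continuum}: a list with
#'   \code{parents}, \code{steps} (length \code{k + 2}, endpoints are the
#'   parents themselves) and \code{k}.
#' @examples
#' a <- make_base(5, seed = 1)
#' b <- make_base(5, seed = 2)
#' cont <- morph_pair(a, b, k = 3)
#' length(cont$steps)  # 5
#' @export
morph_pair <- function(parent1, parent2, k) {
  if (!inherits(parent1, "sc_stimulus") || !inherits(parent2, "sc_stimulus"))
    stop_arg("parents must be sc_stimulus objects")
  if (n_spheres(parent1) != n_spheres(parent2))
    stop_arg("parents must consist of the same number of spheres (got ",
             n_spheres(parent1), " and ", n_spheres(parent2), ")")
  if (!is_count(k, min = 0L)) stop_arg("`k` must be a nonnegative integer")
  k <- as.integer(k)
  s1 <- parent1$spheres
  s2 <- parent2$spheres
  dh <- hue_diff(s2$hue, s1$hue)  # signed shortest arc
  mid <- lapply(seq_len(k), function(j) {
    t <- j / (k + 1)
    sp <- s1
    for (f in c("x", "y", "z", "size", "sat", "val"))
      sp[[f]] <- s1[[f]] + t * (s2[[f]] - s1[[f]])
    sp$size <- pmax(sp$size, SIZE_FLOOR)
    sp$hue <- wrap_hue(s1$hue + t * dh)
    new_stimulus(sp, label = sprintf("morph %d/%d", j, k),
                 lineage = sprintf("morph step %d/%d", j, k))
  })
  structure(list(parents = list(parent1, parent2),
                 steps = c(list(parent1), mid, list(parent2)),
                 k = k),
            class = "sc_continuum")
}

#' @export
print.sc_continuum <- function(x, ...) {
  cat(sprintf("<sc_continuum> %d steps (%d in-between), %d spheres\n",
              length(x$steps), x$k, n_spheres(x$parents[[1]])))
  invisible(x)
}
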
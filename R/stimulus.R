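#' Construct a sphere-cloud stimulus
#'
#' A stimulus is an ordered set of colored spheres in 3D scene space.  Each
#' sphere carries a position (\code{x}, \code{y}, \code{z}; \code{y} is the
#' depth axis in the default 2D display), a radius (\code{size}, scene units)
#' and an HSV color (\code{hue} circular in \code{[0,1)}, \code{sat} and
#' \code{val} in \code{[0,1]}).  Sphere order is meaningful: morphing and
#' deviation measures pair spheres by index.
#'
#' Hue is canonicalized on construction: 1.0 wraps to 0.0 (red sits at both
#' ends of the hue circle).  Other fields are stored as given; use
#' \code{\link{validate_stimulus}} to check the invariants.
#'
#' @param spheres a data.frame with columns \code{x, y, z, size, hue, sat,
#'   val}, one row per sphere.
#' @param label free-text label.
#' @param seed integer seed the stimulus was generated from, or \code{NULL}.
#' @param lineage free-text provenance, e.g. \code{"base"},
#'   \code{"derived:uniform"}, \code{"morph step 3/7"}, \code{"exception"}.
#' @return an object of class \code{sc_stimulus}.
#' @seealso \code{\link{make_base}}, \code{\link{validate_stimulus}},
#'   \code{\link{save_stimulus}}
#' @export
new_stimulus <- function(spheres, label = "", seed = NULL, lineage = "manual") {
  if (!is.data.frame(spheres)) stop_arg("`spheres` must be a data.frame")
  missing_cols <- setdiff(SPHERE_FIELDS, names(spheres))
  if (length(missing_cols) > 0)
    stop_arg("`spheres` is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(spheres) < 1) stop_arg("a stimulus needs at least one sphere")
  spheres <- as.data.frame(spheres)[, SPHERE_FIELDS]
  for (f in SPHERE_FIELDS) spheres[[f]] <- as.numeric(spheres[[f]])
  spheres$hue <- wrap_hue(spheres$hue)
  rownames(spheres) <- NULL
  structure(
    list(spheres = spheres, label = as.character(label),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         lineage = as.character(lineage)),
    class = "sc_stimulus")
}

#' @export
print.sc_stimulus <- function(x, ...) {
  cat(sprintf("<sc_stimulus> %d sphere%s  label='%s'  lineage='%s'%s\n",
              n_spheres(x), if (n_spheres(x) == 1) "" else "s",
              x$label, x$lineage,
              if (is.null(x$seed)) "" else sprintf("  seed=%d", x$seed)))
  print(x$spheres, digits = 4)
  invisible(x)
}

#' Number of spheres in a stimulus
#' @param s an \code{sc_stimulus}.
#' @return integer sphere count.
#' @export
n_spheres <- function(s) nrow(s$spheres)

#' Validate a stimulus against the sphere invariants
#'
#' Checks every sphere for: finite numeric fields, \code{size >= 0.01} (the
#' hard floor below which spheres are barely visible), \code{hue} in
#' \code{[0, 1)} and \code{sat}/\code{val} in \code{[0, 1]}.  Violations are
#' reported, not raised, so the function can be used as a post-generation
#' audit.
#'
#' @param s an \code{sc_stimulus}.
#' @return a data.frame with columns \code{sphere} (index), \code{field} and
#'   \code{message}; zero rows means the stimulus is valid.
#' @examples
#' b <- make_base(4, seed = 1)
#' nrow(validate_stimulus(b)) == 0
#' @export
validate_stimulus <- function(s) {
  if (!inherits(s, "sc_stimulus")) stop_arg("`s` must be an sc_stimulus")
  sp <- s$spheres
  out <- data.frame(sphere = integer(), field = character(),
                    message = character(), stringsAsFactors = FALSE)
  add <- function(i, field, msg) {
    out[nrow(out) + 1L, ] <<- list(i, field, msg)
  }
  for (i in seq_len(nrow(sp))) {
    for (f in SPHERE_FIELDS) {
      v <- sp[[f]][i]
      if (!is.finite(v)) { add(i, f, "not a finite number"); next }
      if (f == "size" && v < SIZE_FLOOR)
        add(i, f, sprintf("size %.6g below floor %.2f", v, SIZE_FLOOR))
      if (f == "hue" && (v < 0 || v >= 1))
        add(i, f, sprintf("hue %.6g outside [0, 1)", v))
      if (f %in% c("sat", "val") && (v < 0 || v > 1))
        add(i, f, sprintf("%s %.6g outside [0, 1]", f, v))
    }
  }
  out
}

clamp_sphere_fields <- function(sp) {
  # enforce hard bounds after sampling; returns list(spheres, n_clamped)
  n_clamped <- 0L
  raw <- sp
  sp$size <- pmax(sp$size, SIZE_FLOOR)
  sp$sat <- pmin(pmax(sp$sat, 0), 1)
  sp$val <- pmin(pmax(sp$val, 0), 1)
  sp$hue <- wrap_hue(sp$hue)
  n_clamped <- sum(raw$size != sp$size) + sum(raw$sat != sp$sat) +
    sum(raw$val != sp$val)
  list(spheres = sp, n_clamped = as.integer(n_clamped))
}
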
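#' View specification for rendering
#'
#' Controls the orthographic camera.  The default view shows the scene along
#' the x-z axes: x maps to the image horizontal, z to the vertical, and y
#' (depth) only determines drawing order — exactly the 2D display regime the
#' stimuli are designed for.  \code{azimuth} rotates the scene about the
#' vertical (z) axis and \code{elevation} about the horizontal (x) axis,
#' both in degrees, before projection.
#'
#' @param azimuth,elevation view rotation angles in degrees.
#' @param width,height canvas size in pixels (at least 16 each).
#' @param show_axes draw grey axis lines through the scene origin?
#' @param background background color (any R color).
#' @param world_radius half-extent of the scene box mapped onto the canvas;
#'   the default 1.5 frames base stimuli sampled in \code{[-1, 1]} with room
#'   for sphere radii and derived-member drift.
#' @param near_positive_y if \code{TRUE} (default) larger y is closer to the
#'   viewer and drawn last; set \code{FALSE} to invert the depth convention.
#' @return an object of class \code{sc_view}.
#' @export
view_spec <- function(azimuth = 0, elevation = 0, width = 512, height = 512,
                      show_axes = FALSE, background = "white",
                      world_radius = 1.5, near_positive_y = TRUE) {
  if (!is_count(width, 16L) || !is_count(height, 16L))
    stop_arg("`width` and `height` must be integers >= 16")
  if (!is.numeric(world_radius) || world_radius <= 0)
    stop_arg("`world_radius` must be positive")
  structure(list(azimuth = as.numeric(azimuth),
                 elevation = as.numeric(elevation),
                 width = as.integer(width), height = as.integer(height),
                 show_axes = isTRUE(show_axes),
                 background = background,
                 world_radius = as.numeric(world_radius),
                 near_positive_y = isTRUE(near_positive_y)),
            class = "sc_view")
}

# rotate scene coordinates; cospi/sinpi keep multiples of 90 deg exact,
# so a full 360 deg turn reproduces the default view bit for bit
rotate_scene <- function(p, azimuth, elevation) {
  ca <- cospi(azimuth / 180); sa <- sinpi(azimuth / 180)
  x <- ca * p$x - sa * p$y
  y <- sa * p$x + ca * p$y
  ce <- cospi(elevation / 180); se <- sinpi(elevation / 180)
  y2 <- ce * y - se * p$z
  z2 <- se * y + ce * p$z
  list(x = x, y = y2, z = z2)
}

#' Render a stimulus to a raster image
#'
#' Deterministic rasterization: the scene is rotated by the view angles,
#' orthographically projected (no perspective — depth must not change
#' apparent size, matching the 2D display regime), and the spheres are drawn
#' back to front by projected depth (painter's algorithm) as shaded discs.
#' Disc radius is proportional to sphere size, fill color is the sphere's
#' HSV color converted to RGB with a fixed radial highlight toward the upper
#' left for a 3D appearance.  Identical inputs give bit-identical output.
#'
#' @param s an \code{sc_stimulus}.
#' @param view a \code{\link{view_spec}}.
#' @return a \code{height x width x 3} numeric array of RGB values in
#'   \code{[0, 1]} (row 1 is the top of the image).
#' @seealso \code{\link{save_image}}
#' @export
render <- function(s, view = view_spec()) {
  if (!inherits(s, "sc_stimulus")) stop_arg("`s` must be an sc_stimulus")
  if (!inherits(view, "sc_view")) stop_arg("`view` must come from view_spec()")
  w <- view$width; h <- view$height
  bg <- as.numeric(grDevices::col2rgb(view$background)) / 255
  img <- array(rep(bg, each = h * w), dim = c(h, w, 3))
  scale <- min(w, h) / (2 * view$world_radius)

  p <- rotate_scene(s$spheres, view$azimuth, view$elevation)
  u <- p$x; v <- p$z; depth <- p$y
  if (!view$near_positive_y) depth <- -depth

  if (view$show_axes) {
    gray <- 0.75
    c0 <- round(w / 2); r0 <- round(h / 2)
    if (c0 >= 1 && c0 <= w) img[, c0, ] <- gray
    if (r0 >= 1 && r0 <= h) img[r0, , ] <- gray
  }

  cols_rgb <- t(grDevices::col2rgb(
    grDevices::hsv(s$spheres$hue, s$spheres$sat, s$spheres$val))) / 255

  # farthest first; stable order so equal depths keep sphere order
  ord <- order(depth)
  for (i in ord) {
    cx <- w / 2 + u[i] * scale          # continuous column coordinate
    cy <- h / 2 - v[i] * scale          # continuous row coordinate
    r <- s$spheres$size[i] * scale
    if (r <= 0) next
    j1 <- max(1L, floor(cx - r)); j2 <- min(w, ceiling(cx + r))
    i1 <- max(1L, floor(cy - r)); i2 <- min(h, ceiling(cy + r))
    if (j1 > j2 || i1 > i2) next   # disc entirely off-canvas
    jr <- j1:j2; ir <- i1:i2
    jc <- jr - 0.5; ic <- ir - 0.5      # pixel centers
    dx <- outer(rep(1, length(ic)), jc - cx)
    dy <- outer(ic - cy, rep(1, length(jc)))
    mask <- dx^2 + dy^2 <= r^2
    if (!any(mask)) next
    # fixed highlight offset toward the upper left; intensity ramps with
    # distance from the highlight point (constants fixed for reproducibility)
    hx <- -0.35 * r; hy <- -0.35 * r
    t <- sqrt((dx - hx)^2 + (dy - hy)^2) / (2 * r)
    shade <- 0.55 + 0.6 * pmax(1 - t, 0)
    glint <- 0.35 * pmax(1 - 3 * t, 0)
    for (ch in 1:3) {
      plane <- img[ir, jr, ch, drop = FALSE]
      dim(plane) <- dim(mask)
      val <- pmin(cols_rgb[i, ch] * shade + glint, 1)
      plane[mask] <- val[mask]
      img[ir, jr, ch] <- plane
    }
  }
  img
}

#' Write a rendered image to disk
#'
#' @param img an RGB array as returned by \code{\link{render}}.
#' @param path output file path.
#' @param format \code{"png"} (lossless) or \code{"jpg"}/\code{"jpeg"};
#'   inferred from the file extension when omitted.  Other formats raise an
#'   unsupported-format error.
#' @return \code{path}, invisibly.
#' @export
save_image <- function(img, path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- tolower(format)
  if (format == "png") {
    png::writePNG(img, target = path)
  } else if (format %in% c("jpg", "jpeg")) {
    jpeg::writeJPEG(img, target = path, quality = 0.95)
  } else {
    stop_arg("unsupported image format '", format,
             "' (supported: png, jpg)")
  }
  invisible(path)
}
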
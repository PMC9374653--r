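stimulus_to_list <- function(s) {
  list(format_version = FORMAT_VERSION,
       kind = "stimulus",
       label = s$label,
       seed = s$seed,
       lineage = s$lineage,
       spheres = lapply(seq_len(n_spheres(s)), function(i)
         as.list(s$spheres[i, SPHERE_FIELDS])))
}

list_to_stimulus <- function(x, where = "") {
  path <- function(p) if (nzchar(where)) paste0(where, p) else p
  if (is.null(x$format_version))
    stop_arg("missing field ", path("format_version"))
  if (!identical(as.character(x$format_version), FORMAT_VERSION))
    stop_arg("unsupported format_version '", x$format_version,
             "' (this build reads version ", FORMAT_VERSION, ")")
  if (is.null(x$spheres) || length(x$spheres) < 1)
    stop_arg("missing or empty field ", path("spheres"))
  rows <- lapply(seq_along(x$spheres), function(i) {
    sp <- x$spheres[[i]]
    for (f in SPHERE_FIELDS)
      if (is.null(sp[[f]]) || !is.numeric(sp[[f]]))
        stop_arg("missing or non-numeric field ",
                 path(sprintf("spheres[%d].%s", i, f)))
    as.data.frame(sp[SPHERE_FIELDS])
  })
  new_stimulus(do.call(rbind, rows),
               label = if (is.null(x$label)) "" else x$label,
               seed = x$seed,
               lineage = if (is.null(x$lineage)) "manual" else x$lineage)
}

#' Save / load a stimulus as JSON
#'
#' The on-disk dialect is a single JSON object
#' \code{\{format_version, kind, label, seed, lineage, spheres: [\{x, y, z,
#' size, hue, sat, val\}, ...]\}} with the sphere array ordered.  Numbers are
#' written at full precision so that \code{load_stimulus(save_stimulus(s))}
#' reproduces \code{s} bit for bit.
#'
#' @param s an \code{sc_stimulus}.
#' @param path file path.
#' @return \code{save_stimulus} returns \code{path} invisibly;
#'   \code{load_stimulus} returns the \code{sc_stimulus}.
#' @export
save_stimulus <- function(s, path) {
  if (!inherits(s, "sc_stimulus")) stop_arg("`s` must be an sc_stimulus")
  jsonlite::write_json(stimulus_to_list(s), path,
                       auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname save_stimulus
#' @export
load_stimulus <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(x$kind) && !identical(x$kind, "stimulus"))
    stop_arg("file is a '", x$kind, "', not a stimulus")
  list_to_stimulus(x)
}

dev_to_list <- function(d) {
  if (is_delta(d)) list(lo = d$lo, hi = d$hi) else list(sigma = d$sigma)
}

list_to_dev <- function(x, mode) {
  if (mode == "uniform") delta_range(x$lo, x$hi) else gauss_spec(x$sigma)
}

#' Save / load a category as JSON
#'
#' A category file embeds the base stimulus, all members and the derivation
#' spec:
#' \code{\{format_version, kind: "category", spec, base, members: [...]\}}.
#'
#' @param cat an \code{sc_category}.
#' @param path file path.
#' @return \code{save_category} returns \code{path} invisibly;
#'   \code{load_category} returns the \code{sc_category}.
#' @export
save_category <- function(cat, path) {
  if (!inherits(cat, "sc_category")) stop_arg("`cat` must be an sc_category")
  spec <- cat$spec
  out <- list(
    format_version = FORMAT_VERSION,
    kind = "category",
    spec = c(list(mode = spec$mode),
             lapply(spec[c("position_shift", "y_dev", "size_dev",
                           "hue_dev", "sat_dev", "val_dev")], dev_to_list)),
    base = stimulus_to_list(cat$base),
    members = lapply(cat$members, stimulus_to_list))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_category
#' @export
load_category <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(as.character(x$format_version), FORMAT_VERSION))
    stop_arg("unsupported format_version '", x$format_version, "'")
  if (!identical(x$kind, "category"))
    stop_arg("file is not a category")
  mode <- x$spec$mode
  spec <- do.call(category_spec, c(
    list(mode = mode),
    lapply(x$spec[c("position_shift", "y_dev", "size_dev", "hue_dev",
                    "sat_dev", "val_dev")], list_to_dev, mode = mode)))
  base <- list_to_stimulus(x$base, where = "base.")
  members <- lapply(seq_along(x$members), function(i)
    list_to_stimulus(x$members[[i]], where = sprintf("members[%d].", i)))
  new_category(base, members, spec)
}
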
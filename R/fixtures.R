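#' Generate the canonical fixture suite
#'
#' Writes a deterministic, seeded set of example artifacts used by the
#' tests, the documentation and CLI smoke runs: an 8-sphere base stimulus, a
#' 40-member uniform-mode category, a 40-member Gaussian-mode category, a
#' 7-step morph continuum (5 in-between stimuli), 5 exceptions via the
#' category-limits route and 5 via a 9-sphere exception base, a
#' within-category deviation table, and PNG renders of representative
#' stimuli.  Two runs with the same seed produce byte-identical JSON.
#'
#' @param dir output directory (created if missing).
#' @param seed master integer seed.
#' @param render_px canvas size for the preview renders, in pixels.
#' @return named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L, render_px = 128L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- fanout_seeds(seed, 8)
  paths <- c()
  put <- function(name, path) {
    paths[name] <<- path
    path
  }

  base <- make_base(8, seed = seeds[1], label = "fixture-base")
  save_stimulus(base, put("base", file.path(dir, "base8.json")))

  uspec <- category_spec("uniform",
                         position_shift = delta_range(0.05, 0.25),
                         y_dev = delta_range(0, 0.1),
                         size_dev = delta_range(0.01, 0.04),
                         hue_dev = delta_range(0, 0.06),
                         sat_dev = delta_range(0, 0.05),
                         val_dev = delta_range(0, 0.05))
  ucat <- generate_category(base, uspec, 40, seed = seeds[2])
  save_category(ucat, put("category_uniform",
                          file.path(dir, "category_uniform.json")))

  gspec <- category_spec("gauss",
                         position_shift = gauss_spec(0.10),
                         y_dev = gauss_spec(0.05),
                         size_dev = gauss_spec(0.02),
                         hue_dev = gauss_spec(0.03),
                         sat_dev = gauss_spec(0.03),
                         val_dev = gauss_spec(0.03))
  gcat <- generate_category(base, gspec, 40, seed = seeds[3])
  save_category(gcat, put("category_gauss",
                          file.path(dir, "category_gauss.json")))

  parent2 <- make_base(8, seed = seeds[4], label = "fixture-parent2")
  cont <- morph_pair(base, parent2, k = 5)
  for (i in seq_along(cont$steps))
    save_stimulus(cont$steps[[i]],
                  put(sprintf("morph_step%02d", i - 1),
                      file.path(dir, sprintf("morph_step%02d.json", i - 1))))

  exc_l <- exceptions_from_limits(
    ucat, dev = list(size = delta_range(0.01, 0.03),
                     x = delta_range(0.05, 0.15),
                     z = delta_range(0.05, 0.15)),
    m = 5, seed = seeds[5])
  for (i in seq_along(exc_l))
    save_stimulus(exc_l[[i]],
                  put(sprintf("exception_limits%02d", i),
                      file.path(dir, sprintf("exception_limits%02d.json", i))))

  exc_base <- make_base(9, seed = seeds[6], label = "fixture-exception-base")
  exc_b <- exceptions_from_base(exc_base, uspec, m = 5, seed = seeds[7])
  for (i in seq_along(exc_b))
    save_stimulus(exc_b[[i]],
                  put(sprintf("exception_base%02d", i),
                      file.path(dir, sprintf("exception_base%02d.json", i))))

  tab <- category_deviation_table(ucat)
  write.csv(tab, put("deviation_table",
                     file.path(dir, "deviation_table.csv")),
            row.names = FALSE)

  view <- view_spec(width = render_px, height = render_px)
  save_image(render(base, view), put("base_png", file.path(dir, "base8.png")))
  save_image(render(ucat$members[[1]], view),
             put("member_png", file.path(dir, "member01.png")))
  save_image(render(cont$steps[[4]], view),
             put("morph_png", file.path(dir, "morph_mid.png")))
  save_image(render(exc_l[[1]], view),
             put("exception_png", file.path(dir, "exception01.png")))

  manifest <- list(command = "make_fixtures", seed = as.integer(seed),
                   package = "spherecloud",
                   version = as.character(utils::packageVersion("spherecloud")),
                   files = as.list(basename(paths)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  paths["manifest"] <- file.path(dir, "manifest.json")
  invisible(paths)
}
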
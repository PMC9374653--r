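# shared builders for test objects; everything is generated in code under
# fixed seeds, nothing is read from disk

one_sphere <- function(x = 0, y = 0, z = 0, size = 0.2, hue = 0.5,
                       sat = 0.9, val = 0.9) {
  new_stimulus(data.frame(x = x, y = y, z = z, size = size,
                          hue = hue, sat = sat, val = val))
}

random_stimulus <- function(n = 5, seed = 1) make_base(n, seed = seed)

uniform_spec <- function(...) category_spec("uniform", ...)
gauss_spec_all <- function(sigma) {
  category_spec("gauss",
                position_shift = gauss_spec(sigma), y_dev = gauss_spec(sigma),
                size_dev = gauss_spec(sigma), hue_dev = gauss_spec(sigma),
                sat_dev = gauss_spec(sigma), val_dev = gauss_spec(sigma))
}

# broad-spread categories where members stray far from their prototype;
# the regime where prototype- and exemplar-protocol difficulty separates
wide_category_world <- function(n_members = 30, seed = 300) {
  spec <- category_spec("uniform",
                        position_shift = delta_range(0.2, 0.9),
                        y_dev = delta_range(0, 0.3),
                        size_dev = delta_range(0, 0.08),
                        hue_dev = delta_range(0, 0.25),
                        sat_dev = delta_range(0, 0.15),
                        val_dev = delta_range(0, 0.15))
  base_a <- make_base(8, seed = seed, label = "protoA")
  base_b <- make_base(8, seed = seed + 1, label = "protoB")
  list(base_a = base_a, base_b = base_b, spec = spec,
       cat_a = generate_category(base_a, spec, n_members, seed = seed + 2),
       cat_b = generate_category(base_b, spec, n_members, seed = seed + 3))
}

# a two-category world for scheduler tests: well-separated bases, members
# with moderate spread
two_category_world <- function(n_members = 30, seed = 100) {
  spec <- category_spec("uniform",
                        position_shift = delta_range(0.05, 0.3),
                        y_dev = delta_range(0, 0.1),
                        size_dev = delta_range(0, 0.03),
                        hue_dev = delta_range(0, 0.08),
                        sat_dev = delta_range(0, 0.05),
                        val_dev = delta_range(0, 0.05))
  base_a <- make_base(8, seed = seed, label = "protoA")
  base_b <- make_base(8, seed = seed + 1, label = "protoB")
  list(base_a = base_a, base_b = base_b, spec = spec,
       cat_a = generate_category(base_a, spec, n_members, seed = seed + 2),
       cat_b = generate_category(base_b, spec, n_members, seed = seed + 3))
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")
cli_path <- function() {
  p <- system.file("exec", "spherecloud", package = "spherecloud")
  if (!nzchar(p) || !file.exists(p))
    p <- system.file("..", "exec", "spherecloud", package = "spherecloud")
  normalizePath(p, mustWork = FALSE)
}
run_cli <- function(args) {
  suppressWarnings(system2(rscript_bin(), c(cli_path(), args),
                           stdout = TRUE, stderr = TRUE))
}
cli_status <- function(args) {
  suppressWarnings(system2(rscript_bin(), c(cli_path(), args),
                           stdout = FALSE, stderr = FALSE))
}
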
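test_that("make_base produces the requested sphere count deterministically", {
  b <- make_base(8, seed = 1)
  expect_equal(n_spheres(b), 8)
  expect_identical(make_base(5, seed = 42)$spheres,
                   make_base(5, seed = 42)$spheres)
  expect_false(identical(make_base(5, seed = 1)$spheres,
                         make_base(5, seed = 2)$spheres))
  expect_error(make_base(0, seed = 1), "positive integer")
  expect_error(base_ranges(size = c(0.3, 0.1)), "lower bound exceeds upper")
  expect_error(base_ranges(size = c(0.001, 0.2)), "within")
})

test_that("base fields respect their sampling ranges", {
  r <- base_ranges(x = c(-0.5, 0.5), size = c(0.1, 0.15), sat = c(0.8, 0.9))
  b <- make_base(200, seed = 3, ranges = r)
  expect_true(all(b$spheres$x >= -0.5 & b$spheres$x <= 0.5))
  expect_true(all(b$spheres$size >= 0.1 & b$spheres$size <= 0.15))
  expect_true(all(b$spheres$sat >= 0.8 & b$spheres$sat <= 0.9))
  expect_true(all(b$spheres$hue >= 0 & b$spheres$hue < 1))
})

test_that("perturb_scalar: zero range is the identity, fixed range forces the magnitude", {
  withr::with_seed(1, {
    expect_equal(perturb_scalar(rep(0.3, 50), delta_range(0, 0), "size"),
                 rep(0.3, 50))
    out <- perturb_scalar(rep(0.3, 200), delta_range(0.1, 0.1), "size")
    expect_true(all(abs(out - 0.3) - 0.1 < 1e-12))
    expect_setequal(round(out, 10), c(0.2, 0.4))
    # both signs actually occur
    expect_true(any(out < 0.3) && any(out > 0.3))
  })
})

test_that("size floor engages: forced -0.05 from base 0.02 stores exactly 0.01", {
  withr::with_seed(2, {
    out <- perturb_scalar(rep(0.02, 100), delta_range(0.05, 0.05), "size")
    expect_true(any(out == 0.01))
    expect_true(all(out %in% c(0.01, 0.07)))
  })
})

test_that("hue wraps on the circle instead of clamping", {
  withr::with_seed(3, {
    out <- perturb_scalar(rep(0.95, 100), delta_range(0.10, 0.10), "circular")
    expect_true(all(abs(out - 0.85) < 1e-12 | abs(out - 0.05) < 1e-12))
    expect_true(any(abs(out - 0.05) < 1e-12))  # the wrapped branch occurs
  })
})

test_that("XZ displacement equals the drawn polar distance for any angle", {
  withr::with_seed(4, {
    x <- runif(500, -1, 1); z <- runif(500, -1, 1)
    out <- shift_position(x, z, delta_range(0.3, 0.3))
    expect_equal(sqrt((out$x - x)^2 + (out$z - z)^2), rep(0.3, 500),
                 tolerance = 1e-12)
    out0 <- shift_position(x, z, delta_range(0, 0))
    expect_equal(out0$x, x)
    expect_equal(out0$z, z)
    outg <- shift_position(x, z, gauss_spec(0.2))
    expect_equal(sqrt((outg$x - x)^2 + (outg$z - z)^2), outg$dist,
                 tolerance = 1e-12)
  })
})

test_that("Gaussian position distances follow the half-normal with mean sigma*sqrt(2/pi)", {
  sigma <- 0.2
  n <- 10000
  # independent oracle: brute-force sampling of |Normal(0, sigma)|
  oracle_mean <- withr::with_seed(99, mean(abs(rnorm(n, 0, sigma))))
  closed_form <- sigma * sqrt(2 / pi)
  expect_equal(oracle_mean, closed_form, tolerance = 3 * sigma / sqrt(n))
  d <- withr::with_seed(5,
    shift_position(numeric(n), numeric(n), gauss_spec(sigma))$dist)
  se <- sigma * sqrt(1 - 2 / pi) / sqrt(n)
  expect_lt(abs(mean(d) - closed_form), 3 * se)
})

test_that("derive_member with all-zero spec reproduces the base", {
  b <- make_base(6, seed = 10)
  m <- derive_member(b, category_spec("uniform"), seed = 11)
  expect_equal(m$spheres, b$spheres, tolerance = 1e-15)
  mg <- derive_member(b, category_spec("gauss"), seed = 12)
  expect_equal(mg$spheres, b$spheres, tolerance = 1e-15)
})

test_that("uniform-mode deviations always stay inside the [lo, hi] band (unclamped hook)", {
  b <- make_base(10, seed = 20)
  spec <- category_spec("uniform",
                        position_shift = delta_range(0.1, 0.4),
                        y_dev = delta_range(0.02, 0.08),
                        size_dev = delta_range(0.02, 0.05),
                        hue_dev = delta_range(0.01, 0.2),
                        sat_dev = delta_range(0, 0.3),
                        val_dev = delta_range(0.05, 0.3))
  for (seed in 1:30) {
    m <- derive_member(b, spec, seed = seed, clamp = FALSE)
    dxz <- sqrt((m$spheres$x - b$spheres$x)^2 + (m$spheres$z - b$spheres$z)^2)
    expect_true(all(dxz >= 0.1 - 1e-12 & dxz <= 0.4 + 1e-12))
    in_band <- function(dev, lo, hi) all(dev >= lo - 1e-12 & dev <= hi + 1e-12)
    expect_true(in_band(abs(m$spheres$y - b$spheres$y), 0.02, 0.08))
    expect_true(in_band(abs(m$spheres$size - b$spheres$size), 0.02, 0.05))
    expect_true(in_band(abs(m$spheres$hue - b$spheres$hue), 0.01, 0.2))
    expect_true(in_band(abs(m$spheres$sat - b$spheres$sat), 0, 0.3))
    expect_true(in_band(abs(m$spheres$val - b$spheres$val), 0.05, 0.3))
  }
})

test_that("no generated sphere ever violates the invariants, even under extreme specs", {
  b <- make_base(8, seed = 30)
  extreme <- list(
    category_spec("uniform", position_shift = delta_range(0, 5),
                  y_dev = delta_range(0, 5), size_dev = delta_range(0, 1),
                  hue_dev = delta_range(0, 3), sat_dev = delta_range(0, 2),
                  val_dev = delta_range(0, 2)),
    gauss_spec_all(2))
  for (spec in extreme)
    for (seed in 1:25)
      expect_equal(nrow(validate_stimulus(derive_member(b, spec, seed))), 0)
})

test_that("Gaussian-mode parameters recover base as mean and sigma as SD", {
  b <- one_sphere(sat = 0.5, val = 0.5, size = 0.5, y = 0)
  sigma <- 0.05
  n <- 2000
  spec <- gauss_spec_all(sigma)
  draws <- vapply(seq_len(n), function(i)
    derive_member(b, spec, seed = i, clamp = FALSE)$spheres$sat, numeric(1))
  expect_lt(abs(mean(draws) - 0.5), 3 * sigma / sqrt(n))
  expect_lt(abs(sd(draws) - sigma), 3 * sigma / sqrt(2 * (n - 1)))
  # distribution-recovery: unclamped draws are Normal(base, sigma)
  ks <- ks.test(draws, "pnorm", mean = 0.5, sd = sigma)
  expect_gt(ks$p.value, 0.01)
})

test_that("generate_category preserves sphere count and is reproducible", {
  b <- make_base(6, seed = 40)
  spec <- category_spec("uniform", size_dev = delta_range(0.02, 0.05))
  cat1 <- generate_category(b, spec, 40, seed = 50)
  expect_length(cat1$members, 40)
  expect_true(all(vapply(cat1$members, n_spheres, integer(1)) == 6))
  cat2 <- generate_category(b, spec, 40, seed = 50)
  for (i in c(1, 20, 40))
    expect_identical(cat1$members[[i]]$spheres, cat2$members[[i]]$spheres)
  expect_error(generate_category(b, spec, 0, seed = 1), "positive integer")
  # members differ from one another (seed fan-out is not degenerate)
  expect_false(identical(cat1$members[[1]]$spheres, cat1$members[[2]]$spheres))
})

test_that("preview exemplars sit at the spec extremes", {
  b <- one_sphere(size = 0.3, sat = 0.5, val = 0.5, hue = 0.5)
  pv <- preview_exemplars(b, category_spec("uniform",
                                           size_dev = delta_range(0.02, 0.05)))
  expect_equal(pv$low$spheres$size, 0.25)
  expect_equal(pv$high$spheres$size, 0.35)

  pv0 <- preview_exemplars(b, category_spec("gauss"))
  expect_equal(pv0$low$spheres, b$spheres)
  expect_equal(pv0$high$spheres, b$spheres)

  # Gaussian previews at the two-sided 5% tail quantiles, vs the normal
  # quantile oracle
  sigma <- 1
  pv1 <- preview_exemplars(b, category_spec("gauss", y_dev = gauss_spec(sigma)))
  expect_equal(pv1$high$spheres$y - b$spheres$y, qnorm(0.975) * sigma)
  expect_equal(pv1$low$spheres$y - b$spheres$y, -qnorm(0.975) * sigma)
  # the tail mass is exposed: 5% per tail reading
  pv2 <- preview_exemplars(b, category_spec("gauss", y_dev = gauss_spec(sigma)),
                           tail_mass = 0.10)
  expect_equal(pv2$high$spheres$y - b$spheres$y, qnorm(0.95) * sigma)
})
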
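test_that("canonical lattice yields a straight axis with the subunit radius", {
  conf <- build_canonical_lattice(lattice_params(n_subunits = 60))
  ax <- fit_axis_spline(conf)
  s <- seq(ax$s_range[1], ax$s_range[2], length.out = 20)
  r <- ax$radius(s)
  expect_true(all(abs(r - 2.5) / 2.5 < 0.02))
  tg <- ax$tangent(s)
  expect_true(all(abs(tg %*% c(0, 0, 1)) > 1 - 1e-9))
})

test_that("collinear input degenerates to the line with radius 0", {
  pos <- cbind(0, 0, seq(0, 27, by = 3))
  ax <- fit_axis_spline(pos)
  expect_true(all(abs(ax$radius(c(0, 5, 10))) < 1e-9))
  rise <- instantaneous_rise(pos, ax)
  expect_equal(as.numeric(rise), rep(30, 9), tolerance = 1e-9)
})

test_that("instantaneous rise matches canonical and programmed profiles", {
  conf <- build_canonical_lattice(lattice_params(n_subunits = 100))
  expect_true(all(abs(instantaneous_rise(conf) - 27.8) < 0.1))
  g <- gen_modulated_lattice(lattice_params(n_subunits = 100),
                             rise_mod = function(i) 2 * sin(2 * pi * i / 20))
  rise <- instantaneous_rise(g$config, fit_axis_spline(g$config))
  expect_true(all(abs(rise - g$truth$rise_A) < 0.3))
})

test_that("instantaneous twist matches canonical, round trips, and flips chirality", {
  conf <- build_canonical_lattice(lattice_params(n_subunits = 100))
  tw <- instantaneous_twist(conf)
  expect_true(all(abs(tw + 166.67) < 0.1))
  g <- gen_modulated_lattice(lattice_params(twist = -165, n_subunits = 60))
  expect_true(all(abs(instantaneous_twist(g$config) + 165) < 0.1))
  mirrored <- conf_coords(conf)
  mirrored[, 1] <- -mirrored[, 1]
  twm <- instantaneous_twist(filament_conf(mirrored))
  expect_true(all(abs(twm - 166.67) < 0.1))
})

test_that("wavelike twist and rise modulations average to the canonical values", {
  p <- lattice_params(n_subunits = 100)
  gt <- gen_modulated_lattice(p, twist_mod = function(i) 5 * sin(2 * pi * i / 20))
  tw <- instantaneous_twist(gt$config, fit_axis_spline(gt$config))
  expect_lt(abs(mean(tw) - (-166.67)), 0.2)
  gr <- gen_modulated_lattice(p,
    rise_mod = function(i) 2 * sin(2 * pi * i / 20 + pi * (i %% 2)))
  prof <- measure_helical_profile(gr$config)
  for (s in 1:2)
    expect_lt(abs(mean(prof$rise_A[prof$strand == s]) - 27.8), 0.1)
})

test_that("rise and twist are invariant under proper rigid motion", {
  g <- gen_modulated_lattice(lattice_params(n_subunits = 60),
                             twist_mod = function(i) 3 * sin(2 * pi * i / 15))
  r1 <- instantaneous_rise(g$config)
  t1 <- instantaneous_twist(g$config)
  moved <- filament_conf(rigid_transform(conf_coords(g$config),
                                         axis = c(1, 2, 0.5)))
  r2 <- instantaneous_rise(moved)
  t2 <- instantaneous_twist(moved)
  expect_equal(as.numeric(r1), as.numeric(r2), tolerance = 1e-6)
  expect_equal(as.numeric(t1), as.numeric(t2), tolerance = 1e-6)
})

test_that("the two twist measurements agree for near-canonical filaments", {
  g <- gen_modulated_lattice(lattice_params(n_subunits = 80),
                             twist_mod = function(i) 2 * sin(2 * pi * i / 25),
                             rise_mod = function(i) 1 * cos(2 * pi * i / 25))
  t1 <- measure_subunit_twist(g$config)
  t2 <- instantaneous_twist(g$config, fit_axis_spline(g$config))
  inner <- 10:70
  expect_true(all(abs(t1[inner] - t2[inner]) < 1))
})

test_that("three-copy stitching reproduces interior values at the edges", {
  conf <- build_canonical_lattice(lattice_params(n_subunits = 40))
  prof <- measure_helical_profile(conf, stitch = 3)
  expect_equal(nrow(prof), 39L)
  expect_true(all(abs(prof$rise_A - 27.8) < 0.05))
  expect_true(all(abs(prof$twist_deg + 166.67) < 0.05))
  st <- stitch_configuration(conf, 3)
  expect_equal(nrow(st), 120L)
  ctr <- attr(st, "central")
  expect_equal(unname(conf_coords(st)[ctr[1]:ctr[2], ]),
               unname(conf_coords(conf)), tolerance = 1e-9)
})

test_that("superhelical axis paths are recovered by the axis spline", {
  g <- gen_modulated_lattice(lattice_params(n_subunits = 300),
    axis_offset = function(z) 10 * c(sin(2 * pi * z / 200), cos(2 * pi * z / 200)))
  ax <- fit_axis_spline(g$config)
  expect_equal(ax$frame, "spline")
  s <- seq(ax$s_range[1] + 10, ax$s_range[2] - 10, length.out = 50)
  pts <- ax$at(s)
  true_ax <- cbind(10 * sin(2 * pi * pts[, 3] / 200),
                   10 * cos(2 * pi * pts[, 3] / 200), pts[, 3])
  expect_lt(max(sqrt(rowSums((pts - true_ax)^2))), 1)
})
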
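test_that("midpoint-projection twist recovers lattice twist", {
  conf <- build_canonical_lattice(lattice_params(n_subunits = 60))
  tw <- measure_subunit_twist(conf)
  expect_equal(length(tw), 59L)
  expect_true(all(abs(tw + 166.67) < 0.05))
  # round trip at a different twist
  g <- gen_modulated_lattice(lattice_params(twist = -160, n_subunits = 50))
  expect_true(all(abs(measure_subunit_twist(g$config) + 160) < 0.1))
  expect_error(measure_subunit_twist(conf_coords(conf)[1:3, ]), "at least 4")
})

test_that("a programmed linear twist gradient is recovered monotonically", {
  grad <- function(i) -10 * i / 49  # -160 at i=0 down to ~-170
  g <- gen_modulated_lattice(lattice_params(twist = -160, n_subunits = 51),
                             twist_mod = grad)
  tw <- measure_subunit_twist(g$config)
  expect_true(all(abs(tw - g$truth$twist_deg) < 0.5))
  fit <- stats::coef(stats::lm(tw ~ seq_along(tw)))
  expect_lt(fit[2], 0)  # monotone decreasing trend
})

test_that("stretch stiffness of a pure serial chain is k/m (springs in series)", {
  m <- 9L  # 9 springs in a 10-particle chain
  pos <- cbind(0, 0, seq(0, by = 2, length.out = m + 1))
  conf <- filament_conf(pos)
  topo <- structure(list(
    bonds = data.frame(i = 0:(m - 1), j = 1:m, type = "lateral", l0 = 2),
    angles = data.frame(j = integer(0), i = integer(0), k = integer(0),
                        theta0 = numeric(0)),
    dihedrals = data.frame(i = integer(0), j = integer(0), k = integer(0),
                           l = integer(0), phi0 = numeric(0), n = integer(0)),
    n_subunits = m + 1L), class = "spring_topology")
  k <- stretch_stiffness(topo, mechanical_params(18, 1, 1), c(0, 1, 2),
                         config = conf, n_fixed = 1L, n_loaded = 1L)
  expect_equal(as.numeric(k), 18 / m, tolerance = 1e-6)
})

test_that("doubling every stiffness doubles the measured stretch stiffness", {
  conf <- build_canonical_lattice(lattice_params(n_subunits = 39))
  topo <- derive_topology(conf)
  k1 <- stretch_stiffness(topo, mechanical_params(200, 200, 200), c(0, 10, 20),
                          config = conf)
  k2 <- stretch_stiffness(topo, mechanical_params(400, 400, 400), c(0, 10, 20),
                          config = conf)
  expect_equal(as.numeric(k2) / as.numeric(k1), 2, tolerance = 0.02)
  # determinism to machine precision
  k1b <- stretch_stiffness(topo, mechanical_params(200, 200, 200), c(0, 10, 20),
                           config = conf)
  expect_identical(as.numeric(k1), as.numeric(k1b))
})

test_that("a one-point stiffness grid is returned with its measurement", {
  sc <- scan_stiffness(300, 300, target = 37, n_subunits = 39L)
  expect_equal(nrow(sc$grid), 1L)
  expect_equal(sc$selected$k_l, 300)
  expect_equal(sc$measured, sc$grid$stiffness[1])
  expect_error(scan_stiffness(numeric(0), 300, 37), "empty")
})

test_that("twist variance is zero for canonical frames and sized by exclusion", {
  n <- 100L
  conf <- build_canonical_lattice(lattice_params(n_subunits = n))
  frames <- array(rep(conf_coords(conf), 3), dim = c(n, 3, 3))
  pr <- twist_variance_profile(list(frames = frames))
  expect_equal(length(pr$variance), 60L)
  expect_true(all(pr$variance < 1e-4))
  expect_true(all(diff(pr$cumulative) >= 0))
  expect_error(twist_variance_profile(list(frames = frames[, , 1, drop = FALSE])),
               "at least 2 frames")
})

test_that("twist variance scales quadratically with injected noise", {
  p <- lattice_params(n_subunits = 60)
  v <- vapply(c(1, 2), function(s) {
    g <- gen_twist_noise_trajectory(p, sigma_deg = s, n_frames = 600, seed = 31)
    mean(twist_variance_profile(g, exclude_terminal = 10L)$variance)
  }, numeric(1))
  expect_equal(v[2] / v[1], 4, tolerance = 0.05)
  # profile is flat for i.i.d. noise: spread small relative to level
  g <- gen_twist_noise_trajectory(p, sigma_deg = 2, n_frames = 600, seed = 32)
  pr <- twist_variance_profile(g, exclude_terminal = 10L)
  expect_lt(stats::sd(pr$variance) / mean(pr$variance), 0.25)
})

test_that("larger k_phi gives smaller thermal twist variance", {
  # explicit small step so the stiff dihedral modes are resolved
  integ <- integrator_params(seed = 12, dt = 0.004, n_steps = 6000L,
                             save_every = 200L)
  v <- vapply(c(500, 4000), function(kphi) {
    mech <- mechanical_params(270, 300, kphi)
    mean(thermal_twist_profile(mech, n_subunits = 60L, integ = integ,
                               exclude_terminal = 10L)$variance)
  }, numeric(1))
  expect_lt(v[2], v[1])
})

test_that("degenerate twist-scan inputs are rejected", {
  expect_error(scan_twist_stiffness(2000, 300, numeric(0), k_l = 270), "empty")
  expect_error(scan_twist_stiffness(numeric(0), 300, c(1, 2), k_l = 270), "empty")
})
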
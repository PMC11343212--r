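test_that("canonical lattice places subunits on the stated helix", {
  p <- lattice_params(rise = 27.8, twist = -166.67, n_subunits = 100)
  conf <- build_canonical_lattice(p)
  pos <- conf_coords(conf, units = "angstrom")
  dz <- diff(pos[, 3])
  expect_equal(dz, rep(27.8, 99), tolerance = 1e-12)
  az <- atan2(pos[, 2], pos[, 1]) * 180 / pi
  daz <- diff(az)
  daz <- ((daz + 180) %% 360) - 180
  expect_equal(daz, rep(-166.67, 99), tolerance = 1e-9)
  r <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  expect_equal(r, rep(25, 100), tolerance = 1e-12)
})

test_that("single-subunit lattice is one point at (r, 0, 0)", {
  conf <- build_canonical_lattice(lattice_params(n_subunits = 1))
  expect_equal(nrow(conf), 1L)
  expect_equal(conf_coords(conf, units = "angstrom")[1, ],
               c(x = 25, y = 0, z = 0), tolerance = 1e-12)
})

test_that("subunit 2 equals two applications of the generating transform", {
  p <- lattice_params(rise = 27.8, twist = -166.67, n_subunits = 3)
  pos <- conf_coords(build_canonical_lattice(p), units = "angstrom")
  th <- -166.67 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  step <- function(v) as.vector(R %*% v) + c(0, 0, 27.8)
  expect_equal(unname(pos[3, ]), step(step(pos[1, ])), tolerance = 1e-10)
})

test_that("invalid lattice parameters are rejected", {
  expect_error(lattice_params(rise = -1), "rise")
  expect_error(lattice_params(twist = 200), "twist|180")
  expect_error(lattice_params(radius = 0), "radius")
  expect_error(lattice_params(n_subunits = 0), "n_subunits")
  expect_error(filament_conf(matrix(c(0, 0, 0, 0, 0, 0), 2, 3, byrow = TRUE)),
               "coincide")
  expect_error(filament_conf(matrix(c(0, 0, NA), 1, 3)), "finite")
})

test_that("topology has the stated bond, angle and dihedral structure", {
  conf <- build_canonical_lattice(lattice_params(n_subunits = 100))
  topo <- derive_topology(conf)
  # interior particles (0-based 2..97) are the vertex of exactly 6 angles
  cnt <- table(topo$angles$i)
  expect_equal(sort(as.integer(names(cnt))), 2:97)
  expect_true(all(cnt == 6L))
  # two dihedrals per leading particle where both helical paths fit
  dcnt <- table(topo$dihedrals$i)
  expect_true(all(dcnt[as.character(0:93)] == 2L))
  # 10-subunit chain: 9 lateral + 8 axial bonds
  t10 <- derive_topology(build_canonical_lattice(lattice_params(n_subunits = 10)))
  expect_equal(nrow(t10$bonds), 17L)
  expect_equal(sum(t10$bonds$type == "lateral"), 9L)
  expect_equal(sum(t10$bonds$type == "axial"), 8L)
  expect_error(derive_topology(build_canonical_lattice(lattice_params(n_subunits = 6))),
               "at least 7")
})

test_that("generating configuration is the exact zero of the derived network", {
  fx <- canonical_fixture(40)
  expect_lt(total_energy(fx$conf, fx$topo, fx$mech), 1e-18)
})

test_that("topology derivation is deterministic", {
  conf <- build_canonical_lattice(lattice_params(n_subunits = 30))
  t1 <- derive_topology(conf)
  t2 <- derive_topology(conf)
  expect_identical(t1, t2)
})

test_that("lattice round trip: measured rise and twist return the inputs", {
  p <- lattice_params(rise = 27.8, twist = -166.67, n_subunits = 100)
  conf <- build_canonical_lattice(p)
  ax <- fit_axis_spline(conf)
  rise <- instantaneous_rise(conf, ax)
  twist <- instantaneous_twist(conf, ax)
  expect_equal(as.numeric(rise), rep(27.8, 99), tolerance = 1e-9)
  expect_equal(as.numeric(twist), rep(-166.67, 99), tolerance = 1e-9)
})

test_that("configuration IO round trips through XYZ and CSV", {
  conf <- build_canonical_lattice(lattice_params(n_subunits = 12))
  fx <- tempfile(fileext = ".xyz")
  write_xyz(conf, fx)
  lines <- readLines(fx)
  expect_equal(as.integer(lines[1]), 12L)
  fc <- tempfile(fileext = ".csv")
  write_centroid_csv(conf, fc)
  back <- read_markers_csv(fc, units = "angstrom")
  expect_equal(unname(back), unname(conf_coords(conf)), tolerance = 1e-6)
  cfgf <- tempfile(fileext = ".cfg")
  writeLines(c("rise = 27.8", "# comment", "twist = -166.67", "label = canonical"),
             cfgf)
  cfg <- read_config_file(cfgf)
  expect_equal(cfg$rise, 27.8)
  expect_equal(cfg$twist, -166.67)
  expect_equal(cfg$label, "canonical")
})
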
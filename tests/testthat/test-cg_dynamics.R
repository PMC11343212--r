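test_that("energy matches trivial closed forms", {
  fx <- canonical_fixture(40)
  expect_lt(total_energy(fx$conf, fx$topo, fx$mech), 1e-18)
  # single stretched bond: 1/2 * 10 * 0.1^2 = 0.05 pN nm
  conf2 <- filament_conf(matrix(c(0, 0, 0, 0, 0, 1.1), 2, 3, byrow = TRUE))
  topo2 <- structure(list(
    bonds = data.frame(i = 0L, j = 1L, type = "lateral", l0 = 1.0),
    angles = data.frame(j = integer(0), i = integer(0), k = integer(0),
                        theta0 = numeric(0)),
    dihedrals = data.frame(i = integer(0), j = integer(0), k = integer(0),
                           l = integer(0), phi0 = numeric(0), n = integer(0)),
    n_subunits = 2L), class = "spring_topology")
  mech2 <- mechanical_params(10, 1, 1)
  expect_equal(total_energy(conf2, topo2, mech2), 0.05, tolerance = 1e-12)
  f <- compute_forces(conf2, topo2, mech2)
  expect_equal(f[1, ], c(0, 0, 1), tolerance = 1e-12)  # k dl toward partner
  expect_equal(f[2, ], c(0, 0, -1), tolerance = 1e-12)
})

test_that("energy of a perturbed lattice matches the literal-transcription oracle", {
  fx <- canonical_fixture(30)
  set.seed(11)
  pos <- conf_coords(fx$conf) + matrix(rnorm(90, sd = 0.05), ncol = 3)
  E <- total_energy(filament_conf(pos), fx$topo, fx$mech)
  expect_equal(E, oracle_energy(pos, fx$topo, fx$mech), tolerance = 1e-10)
  expect_gt(E, 0)
})

test_that("energy is invariant under rigid motion", {
  fx <- canonical_fixture(25)
  set.seed(4)
  pos <- conf_coords(fx$conf) + matrix(rnorm(75, sd = 0.03), ncol = 3)
  E1 <- total_energy(filament_conf(pos), fx$topo, fx$mech)
  E2 <- total_energy(filament_conf(rigid_transform(pos)), fx$topo, fx$mech)
  expect_equal(E1, E2, tolerance = 1e-9)
})

test_that("forces are the analytic negative gradient (finite-difference oracle)", {
  fx <- canonical_fixture(20)
  expect_equal(max(abs(compute_forces(fx$conf, fx$topo, fx$mech))), 0,
               tolerance = 1e-10)
  set.seed(21)
  pos <- conf_coords(fx$conf) + matrix(rnorm(60, sd = 0.05), ncol = 3)
  cfg <- filament_conf(pos)
  f <- compute_forces(cfg, fx$topo, fx$mech)
  fd <- oracle_fd_forces(cfg, fx$topo, fx$mech)
  expect_lt(max(abs(f - fd)), 1e-4)
  # internal forces: zero net force and torque
  expect_lt(max(abs(colSums(f))), 1e-9)
  tq <- colSums(cbind(pos[, 2] * f[, 3] - pos[, 3] * f[, 2],
                      pos[, 3] * f[, 1] - pos[, 1] * f[, 3],
                      pos[, 1] * f[, 2] - pos[, 2] * f[, 1]))
  expect_lt(max(abs(tq)), 1e-8)
})

test_that("zero-force NVE run stays at equilibrium", {
  fx <- canonical_fixture(20)
  traj <- run_dynamics(fx$conf, fx$topo, fx$mech,
                       force_protocol("constant", "tension", per_particle_force = 0,
                                      n_fixed = 0L, n_loaded = 1L),
                       integrator_params(thermostat_on = FALSE, seed = 1,
                                         n_steps = 2000L, save_every = 500L,
                                         dt = 1e-3))
  drift <- apply(traj$frames, 3, function(f) max(abs(f - conf_coords(fx$conf))))
  expect_lt(max(drift), 1e-10)
})

test_that("NVE energy drift of a perturbed filament is below 0.1%", {
  conf <- build_canonical_lattice(lattice_params(n_subunits = 30))
  topo <- derive_topology(conf)
  mech <- calibrated_params("ADP")
  set.seed(3)
  pert <- filament_conf(conf_coords(conf) + matrix(rnorm(90, sd = 0.01), ncol = 3))
  E0 <- total_energy(pert, topo, mech)
  arr <- spiractin:::topo_arrays(topo, mech)
  res <- spiractin:::cg_langevin_cpp(conf_coords(pert), matrix(0, 30, 3),
    arr$bonds, arr$l0, arr$kl, arr$angles, arr$th0, arr$kth,
    arr$dihedrals, arr$ph0, arr$kph, arr$mult,
    matrix(0, 30, 3), integer(0), 1e-4, 0, 0, 1, 10000L, 10000L, 1e6)
  Etot <- total_energy(filament_conf(res$pos), topo, mech) + 0.5 * sum(res$vel^2)
  expect_lt(abs(Etot - E0) / E0, 1e-3)
})

test_that("thermostatted bond samples the analytic harmonic variance", {
  b <- matrix(c(0L, 1L), 1, 2)
  e3 <- matrix(integer(0), 0, 3); e4 <- matrix(integer(0), 0, 4)
  ev <- numeric(0); ei <- integer(0)
  set.seed(7)
  res <- spiractin:::cg_langevin_cpp(
    matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE), matrix(0, 2, 3),
    b, 5.0, 5.0, e3, ev, ev, e4, ev, ev, ei,
    matrix(0, 2, 3), 0L, 0.005, 5, 4.11, 1, 400000L, 50L, 1e6)
  r <- sqrt(colSums(res$frames[2, , ]^2))
  r <- r[1000:8000]
  expect_equal(var(r), 4.11 / 5, tolerance = 0.12)
})

test_that("trajectories are reproducible and respect the protocol", {
  conf <- build_canonical_lattice(lattice_params(n_subunits = 30))
  topo <- derive_topology(conf)
  mech <- calibrated_params("ADP")
  prot <- force_protocol("constant", "tension")
  integ <- integrator_params(seed = 9, n_steps = 2000L, save_every = 500L)
  t1 <- run_dynamics(conf, topo, mech, prot, integ)
  t2 <- run_dynamics(conf, topo, mech, prot, integ)
  expect_identical(t1$frames, t2$frames)
  # fixed particles never move
  for (f in seq_len(dim(t1$frames)[3]))
    expect_equal(t1$frames[1:5, , f], unname(conf_coords(conf)[1:5, ]),
                 tolerance = 1e-14, ignore_attr = TRUE)
  # times strictly increasing
  expect_true(all(diff(t1$times) > 0))
  expect_error(force_protocol("constant", "tension", per_particle_force = -1),
               ">= 0")
  expect_error(run_dynamics(conf, topo, mech,
                            force_protocol("constant", "tension",
                                           n_loaded = 20L, n_fixed = 15L),
                            integ), "n_loaded")
})

test_that("apply_release trajectories record both phases and classify spirals", {
  conf <- build_canonical_lattice(lattice_params(n_subunits = 30))
  topo <- derive_topology(conf)
  mech <- calibrated_params("ADP")
  traj <- run_dynamics(conf, topo, mech,
                       force_protocol("apply_release", "tension",
                                      apply_steps = 1000L, release_steps = 1000L),
                       integrator_params(seed = 2, save_every = 500L))
  expect_equal(as.character(unique(traj$phase)), c("apply", "release"))
  tr <- transient_response(traj)
  expect_false(tr$spiral_formed)  # far too short and stiff to spiral
  expect_true(is.na(tr$phase))
  # a trajectory without release frames is rejected
  fake <- traj
  fake$phase <- factor(rep("apply", length(traj$phase)),
                       levels = c("apply", "release"))
  expect_error(transient_response(fake), "release")
})

test_that("trajectory XYZ writer round trips frames, times and phases", {
  conf <- build_canonical_lattice(lattice_params(n_subunits = 12))
  topo <- derive_topology(conf)
  mech <- calibrated_params("ADP")
  traj <- run_dynamics(conf, topo, mech,
                       force_protocol("constant", "tension"),
                       integrator_params(seed = 3, n_steps = 600L, save_every = 200L))
  f <- tempfile(fileext = ".xyz")
  write_trajectory_xyz(traj, f)
  back <- read_trajectory_xyz(f)
  expect_equal(back$frames, unname(traj$frames), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$times, traj$times, tolerance = 1e-6)
  expect_equal(back$phase, as.character(traj$phase))
})
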
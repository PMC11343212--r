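#' @useDynLib spiractin, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats prcomp optim setNames rnorm runif sd var ks.test
#' @importFrom utils combn read.csv write.csv head tail
NULL

kB_pN_nm <- 1.380649e-2  # Boltzmann constant, pN nm / K

#' Default per-particle friction from Stokes' law
#'
#' Friction coefficient 6 pi eta r for a sphere of the given radius in
#' water at room temperature (eta = 8.9e-4 Pa s).
#'
#' @param radius_nm sphere radius in nm (default: canonical subunit radius).
#' @return friction in pN ns / nm.
#' @export
stokes_friction <- function(radius_nm = 2.5) {
  eta <- 8.9e-4                      # Pa s
  6 * pi * eta * radius_nm * 1e3     # 1 N s/m = 1e12 pN ns/nm; r in nm = 1e-9 m
}

#' External force protocol for filament simulations
#'
#' Mimics myosin loading: the first `n_fixed` subunits are immobilised and
#' each of the last `n_loaded` subunits receives an axial force of
#' `per_particle_force` pN (5 pN each across five subunits approximates a
#' single myosin, 25 pN total). `tension` pulls away from the fixed end
#' along the initial filament axis, `compression` pushes toward it. In
#' `apply_release` mode the external force is dropped after the apply phase.
#'
#' @param mode `"constant"` or `"apply_release"`.
#' @param sense `"tension"` or `"compression"`.
#' @param per_particle_force force per loaded subunit, pN.
#' @param n_loaded,n_fixed subunit counts at the two ends.
#' @param apply_steps,release_steps step counts for the two phases of
#'   `apply_release` mode; `NULL` apply_steps means "run until the
#'   end-to-end extension plateaus", and `NULL` release_steps copies the
#'   apply duration.
#' @return a `force_protocol` object.
#' @export
force_protocol <- function(mode = c("constant", "apply_release"),
                           sense = c("tension", "compression"),
                           per_particle_force = 5,
                           n_loaded = 5L, n_fixed = 5L,
                           apply_steps = NULL, release_steps = NULL) {
  mode <- match.arg(mode)
  sense <- match.arg(sense)
  if (per_particle_force < 0) stop("per_particle_force must be >= 0")
  structure(list(mode = mode, sense = sense,
                 per_particle_force = per_particle_force,
                 n_loaded = as.integer(n_loaded), n_fixed = as.integer(n_fixed),
                 apply_steps = apply_steps, release_steps = release_steps),
            class = "force_protocol")
}

#' Langevin integrator parameters
#'
#' @param dt time step, ns. `NULL` picks 1/20 of the fastest harmonic
#'   period implied by (k_l, mass) at run time.
#' @param temperature K.
#' @param friction per-particle friction, pN ns / nm ([stokes_friction()]).
#' @param thermostat_on logical; `FALSE` gives NVE velocity-Verlet
#'   (vacuum dynamics).
#' @param seed RNG seed applied at the start of the run.
#' @param n_steps total integration steps.
#' @param save_every frame stride.
#' @param mass nominal particle mass, pN ns^2 / nm. Only configurational
#'   statistics matter for this model, so the mass is a numerical choice.
#' @return an `integrator_params` object.
#' @export
integrator_params <- function(dt = NULL, temperature = 298, friction = stokes_friction(),
                              thermostat_on = TRUE, seed = 1L,
                              n_steps = 10000L, save_every = 100L, mass = 1) {
  if (!is.null(dt) && dt <= 0) stop("dt must be > 0")
  if (temperature < 0) stop("temperature must be >= 0")
  if (thermostat_on && friction <= 0) stop("friction must be > 0 when thermostat is on")
  structure(list(dt = dt, temperature = temperature, friction = friction,
                 thermostat_on = thermostat_on, seed = as.integer(seed),
                 n_steps = as.integer(n_steps), save_every = as.integer(save_every),
                 mass = mass),
            class = "integrator_params")
}

default_dt <- function(mech, mass) {
  kmax <- max(mech$k_l, mech$k_l_axial)
  2 * pi * sqrt(mass / kmax) / 20
}

# unit vector of the initial filament axis (fixed-end centroid -> loaded-end
# centroid); the external force direction is held fixed along it.
initial_axis <- function(config, protocol) {
  pos <- conf_coords(config)
  n <- nrow(pos)
  a <- colMeans(pos[seq_len(protocol$n_fixed), , drop = FALSE])
  b <- colMeans(pos[(n - protocol$n_loaded + 1):n, , drop = FALSE])
  v <- b - a
  v / sqrt(sum(v^2))
}

ext_force_matrix <- function(config, protocol, on = TRUE) {
  pos <- conf_coords(config)
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  if (on && protocol$per_particle_force > 0) {
    axis <- initial_axis(config, protocol)
    sgn <- if (protocol$sense == "tension") 1 else -1
    loaded <- (n - protocol$n_loaded + 1):n
    f[loaded, ] <- matrix(sgn * protocol$per_particle_force * axis,
                          length(loaded), 3, byrow = TRUE)
  }
  f
}

# end-to-end extension projected on the initial axis
axial_extension <- function(pos, protocol, axis) {
  n <- nrow(pos)
  a <- colMeans(pos[seq_len(protocol$n_fixed), , drop = FALSE])
  b <- colMeans(pos[(n - protocol$n_loaded + 1):n, , drop = FALSE])
  sum((b - a) * axis)
}

run_phase <- function(pos, vel, arr, extF, fixed0, integ, dt, n_steps) {
  kBT <- if (integ$thermostat_on) kB_pN_nm * integ$temperature else 0
  gamma <- if (integ$thermostat_on) integ$friction else 0
  cg_langevin_cpp(pos, vel, arr$bonds, arr$l0, arr$kl,
                  arr$angles, arr$th0, arr$kth,
                  arr$dihedrals, arr$ph0, arr$kph, arr$mult,
                  extF, fixed0, dt, gamma, kBT, integ$mass,
                  n_steps, integ$save_every, blow_up = 1e6)
}

#' Simulate filament dynamics under a force protocol
#'
#' Integrates Langevin (or NVE) dynamics of the spring network with the
#' first `n_fixed` subunits immobilised and an axial external force on the
#' last `n_loaded` subunits according to the protocol. Bit-reproducible for
#' a given seed.
#'
#' @param config0 starting [filament_conf()].
#' @param topo matching [derive_topology()] result.
#' @param mech [mechanical_params()].
#' @param protocol [force_protocol()].
#' @param integ [integrator_params()].
#' @return a `cg_trajectory`: list with `frames` (n x 3 x nframes array,
#'   nm), `times` (ns), `phase` (factor `"apply"`/`"release"` per frame),
#'   `protocol`, `integ`, `config0`.
#' @export
run_dynamics <- function(config0, topo, mech, protocol, integ) {
  stopifnot(inherits(protocol, "force_protocol"), inherits(integ, "integrator_params"))
  n <- nrow(config0)
  if (protocol$n_loaded + protocol$n_fixed >= n)
    stop("n_loaded + n_fixed must be < n_subunits")
  arr <- topo_arrays(topo, mech)
  dt <- if (is.null(integ$dt)) default_dt(mech, integ$mass) else integ$dt
  fixed0 <- seq_len(protocol$n_fixed) - 1L
  pos <- conf_coords(config0)
  vel <- matrix(0, n, 3)
  set.seed(integ$seed)

  if (protocol$mode == "constant") {
    res <- run_phase(pos, vel, arr, ext_force_matrix(config0, protocol), fixed0,
                     integ, dt, integ$n_steps)
    frames <- array(res$frames, dim = c(n, 3, integ$n_steps %/% integ$save_every))
    phase <- rep("apply", dim(frames)[3])
  } else {
    apply_steps <- protocol$apply_steps
    extF <- ext_force_matrix(config0, protocol)
    if (is.null(apply_steps)) {
      # run in chunks until the axial extension change plateaus
      axis <- initial_axis(config0, protocol)
      chunk <- max(integ$save_every * 10L, 1000L)
      chunk <- (chunk %/% integ$save_every) * integ$save_every
      frames_list <- list(); ext_prev <- axial_extension(pos, protocol, axis)
      total <- 0L
      repeat {
        res <- run_phase(pos, vel, arr, extF, fixed0, integ, dt, chunk)
        pos <- res$pos; vel <- res$vel
        frames_list[[length(frames_list) + 1L]] <- res$frames
        total <- total + chunk
        ext_now <- axial_extension(pos, protocol, axis)
        if (abs(ext_now - ext_prev) < 0.05 || total >= integ$n_steps) break
        ext_prev <- ext_now
      }
      apply_frames <- array(unlist(frames_list),
                            dim = c(n, 3, total %/% integ$save_every))
      apply_steps <- total
    } else {
      res <- run_phase(pos, vel, arr, extF, fixed0, integ, dt, apply_steps)
      pos <- res$pos; vel <- res$vel
      apply_frames <- array(res$frames, dim = c(n, 3, apply_steps %/% integ$save_every))
    }
    release_steps <- if (is.null(protocol$release_steps)) apply_steps else
      protocol$release_steps
    res <- run_phase(pos, vel, arr, ext_force_matrix(config0, protocol, on = FALSE),
                     fixed0, integ, dt, release_steps)
    rel_frames <- array(res$frames, dim = c(n, 3, release_steps %/% integ$save_every))
    frames <- array(c(apply_frames, rel_frames),
                    dim = c(n, 3, dim(apply_frames)[3] + dim(rel_frames)[3]))
    phase <- rep(c("apply", "release"), c(dim(apply_frames)[3], dim(rel_frames)[3]))
  }

  structure(list(frames = frames,
                 times = dt * integ$save_every * seq_len(dim(frames)[3]),
                 phase = factor(phase, levels = c("apply", "release")),
                 protocol = protocol, integ = integ, dt = dt,
                 config0 = config0),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("CG trajectory: %d frames of %d subunits (%s %s, %.3g ns/frame)\n",
              dim(x$frames)[3], dim(x$frames)[1],
              x$protocol$mode, x$protocol$sense, diff(x$times[1:2])))
  invisible(x)
}

#' Extract one frame of a trajectory as a filament configuration
#' @param traj a `cg_trajectory`.
#' @param i frame index (default: last frame).
#' @return a [filament_conf()].
#' @export
trajectory_frame <- function(traj, i = dim(traj$frames)[3]) {
  filament_conf(traj$frames[, , i])
}

#' Transverse trace amplitude of a filament configuration
#'
#' Fits the central-axis midpoints of the configuration, removes the mean,
#' and reports the largest absolute excursion along the second principal
#' component, in nm. This is the amplitude against which the 15 nm
#' superhelix significance cutoff is applied.
#'
#' @param config a [filament_conf()] (or plain n x 3 matrix in nm).
#' @return amplitude in nm.
#' @export
trace_amplitude <- function(config) {
  pts <- central_axis_points(conf_coords(as_conf_matrix(config)))
  p <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  max(abs(p$x[, 2]))
}

as_conf_matrix <- function(config) {
  if (inherits(config, "filament_conf")) config else filament_conf(config)
}

#' Classify the spiral response of an apply/release trajectory
#'
#' Evaluates the transverse trace amplitude frame by frame and reports
#' whether it crosses the 15 nm significance cutoff, and in which protocol
#' phase the crossing (or the maximum) occurs.
#'
#' @param traj a `cg_trajectory` from [run_dynamics()].
#' @param cutoff_nm amplitude significance cutoff (default 15 nm).
#' @param stride evaluate every `stride`-th frame.
#' @return list with `spiral_formed` (logical), `phase` (`"apply"`,
#'   `"release"` or `NA`), `max_amplitude` (nm) and the per-frame
#'   `amplitude` series.
#' @export
transient_response <- function(traj, cutoff_nm = 15, stride = 1L) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (traj$protocol$mode == "apply_release" && !any(traj$phase == "release"))
    stop("trajectory lacks release frames")
  idx <- seq(1L, dim(traj$frames)[3], by = stride)
  amp <- vapply(idx, function(i) trace_amplitude(traj$frames[, , i]), numeric(1))
  crossed <- amp >= cutoff_nm
  if (any(crossed)) {
    first <- idx[which(crossed)[1]]
    list(spiral_formed = TRUE, phase = as.character(traj$phase[first]),
         max_amplitude = max(amp),
         amplitude = stats::setNames(amp, idx))
  } else {
    list(spiral_formed = FALSE, phase = NA_character_,
         max_amplitude = max(amp),
         amplitude = stats::setNames(amp, idx))
  }
}

#' Deterministically relax a filament to mechanical equilibrium
#'
#' Minimises the elastic energy minus the work of the external force over
#' the positions of the free particles (L-BFGS with the analytic gradient),
#' holding `fixed` particles in place. Used for vacuum force-extension
#' measurements.
#'
#' @param config starting [filament_conf()].
#' @param topo,mech network and stiffness.
#' @param fixed 1-based indices of immobilised particles.
#' @param ext_force n x 3 external force matrix, pN (0 rows elsewhere).
#' @param tol residual max-force convergence tolerance, pN.
#' @param maxit L-BFGS iteration cap per cycle.
#' @return list(config = relaxed [filament_conf()], residual = max residual
#'   force on free particles in pN, converged = logical).
#' @export
relax_filament <- function(config, topo, mech, fixed = integer(0),
                           ext_force = NULL, tol = 1e-6, maxit = 20000L) {
  pos <- conf_coords(config)
  n <- nrow(pos)
  if (is.null(ext_force)) ext_force <- matrix(0, n, 3)
  arr <- topo_arrays(topo, mech)
  free <- setdiff(seq_len(n), fixed)
  full <- pos

  obj <- function(par) {
    full[free, ] <- matrix(par, ncol = 3)
    cg_energy_cpp(full, arr$bonds, arr$l0, arr$kl, arr$angles, arr$th0, arr$kth,
                  arr$dihedrals, arr$ph0, arr$kph, arr$mult) -
      sum(ext_force[free, ] * full[free, ])
  }
  grad <- function(par) {
    full[free, ] <- matrix(par, ncol = 3)
    f <- cg_forces_cpp(full, arr$bonds, arr$l0, arr$kl, arr$angles, arr$th0, arr$kth,
                       arr$dihedrals, arr$ph0, arr$kph, arr$mult)
    -as.vector(f[free, ] + ext_force[free, ])
  }
  par <- as.vector(pos[free, ])
  for (cycle in 1:8) {
    res <- stats::optim(par, obj, grad, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 10))
    par <- res$par
    if (max(abs(grad(par))) < tol) break
  }
  full[free, ] <- matrix(par, ncol = 3)
  residual <- max(abs(grad(par)))
  out <- filament_conf(full)
  # forces at the pN scale: residual below 1e-3 pN shifts the equilibrium
  # extension by < 1e-5 nm, far inside measurement precision
  list(config = out, residual = residual, converged = residual < max(tol, 1e-3))
}
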
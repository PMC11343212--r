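#' Central-axis points by the midpoint construction
#'
#' The filament's central axis is located from subunit centroids by two
#' rounds of midpointing: centroids of consecutive subunit pairs are
#' joined by segments, and the midpoints of neighbouring segments trace
#' the axis. For an n-subunit chain this yields n - 2 axis points that sit
#' within a fraction of an Angstrom of the true helix axis.
#'
#' @param pos n x 3 matrix of subunit positions (nm).
#' @return (n - 2) x 3 matrix of axis points (nm).
#' @export
central_axis_points <- function(pos) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (n < 4) stop("need at least 4 subunits")
  cmid <- (pos[-n, , drop = FALSE] + pos[-1, , drop = FALSE]) / 2
  (cmid[-nrow(cmid), , drop = FALSE] + cmid[-1, , drop = FALSE]) / 2
}

#' Per-interface subunit twist by midpoint projection
#'
#' Implements the midpoint-projection twist measurement: centroids of
#' consecutive subunit pairs are found, neighbouring centroids are joined
#' by segments, midpoints of neighbouring segments are joined into axis
#' segments, each consecutive-subunit pair is projected onto the nearest
#' axis segment, and the twist at that interface is the signed angle
#' between the two projection (rejection) vectors about the axis segment.
#'
#' @param frame a [filament_conf()] (or n x 3 matrix, nm) with >= 4 subunits.
#' @return numeric vector of n - 1 interface twists in degrees, signed
#'   (left-handed genetic helix is negative).
#' @export
measure_subunit_twist <- function(frame) {
  pos <- conf_coords(as_conf_matrix(frame))
  n <- nrow(pos)
  if (n < 4) stop("need at least 4 subunits")
  m <- central_axis_points(pos)                    # n-2 axis points
  if (n >= 8) {
    # extend the axis by the filament's own mean screw transform so the
    # terminal interfaces also face a properly centred axis segment
    cmid <- (pos[-n, , drop = FALSE] + pos[-1, , drop = FALSE]) / 2
    k <- nrow(cmid)
    fit <- kabsch(cmid[-k, , drop = FALSE], cmid[-1, , drop = FALSE])
    m_post <- sweep(m[nrow(m), , drop = FALSE] %*% fit$R, 2, fit$t, "+")
    m_pre <- sweep(m[1, , drop = FALSE], 2, fit$t) %*% t(fit$R)
    m <- rbind(m_pre, m, m_post)
  }
  seg_a <- m[-nrow(m), , drop = FALSE]             # axis segment starts
  seg_b <- m[-1, , drop = FALSE]                   # axis segment ends
  seg_mid <- (seg_a + seg_b) / 2
  d <- seg_b - seg_a
  dlen2 <- rowSums(d^2)
  if (any(dlen2 == 0)) stop("collapsed axis segment at interface ",
                            which(dlen2 == 0)[1])

  twist <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    pmid <- (pos[i, ] + pos[i + 1, ]) / 2
    k <- which.min(rowSums(sweep(seg_mid, 2, pmid)^2))  # nearest axis segment
    dk <- d[k, ] / sqrt(dlen2[k])
    rej <- function(p) {
      v <- p - seg_a[k, ]
      v - sum(v * dk) * dk
    }
    u <- rej(pos[i, ])
    v <- rej(pos[i + 1, ])
    cr <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    twist[i] <- atan2(sum(cr * dk), sum(u * v)) * 180 / pi
  }
  twist
}

#' Stretch stiffness of a filament from vacuum force-extension
#'
#' Relaxes the filament deterministically (no thermostat) to mechanical
#' equilibrium under each axial tension, with the first `n_fixed` subunits
#' held and the pulling force spread over the last `n_loaded` subunits,
#' then fits the least-squares slope of total pulling force against the
#' equilibrium axial extension.
#'
#' @param config equilibrium [filament_conf()] (default: canonical
#'   39-subunit lattice, the classic force-extension geometry).
#' @param topo,mech network topology and stiffness constants.
#' @param tensions total axial tensions in pN (>= 3 values).
#' @param n_fixed,n_loaded end-group sizes.
#' @return stiffness in pN/nm, with attributes `extensions` (nm) and
#'   `tensions` (pN).
#' @export
stretch_stiffness <- function(topo, mech, tensions = c(0, 10, 20),
                              config = NULL, n_fixed = 5L, n_loaded = 5L) {
  if (length(tensions) < 3) stop("need at least 3 tension values")
  if (is.null(config))
    config <- build_canonical_lattice(lattice_params(n_subunits = topo$n_subunits))
  n <- nrow(config)
  protocol <- force_protocol("constant", "tension", per_particle_force = 0,
                             n_loaded = n_loaded, n_fixed = n_fixed)
  axis <- initial_axis(config, protocol)
  loaded <- (n - n_loaded + 1):n
  ext <- vapply(tensions, function(Ft) {
    f <- matrix(0, n, 3)
    f[loaded, ] <- matrix(Ft / n_loaded * axis, n_loaded, 3, byrow = TRUE)
    rel <- relax_filament(config, topo, mech, fixed = seq_len(n_fixed),
                          ext_force = f)
    if (!rel$converged)
      stop(sprintf("relaxation did not converge (residual %.3g pN)", rel$residual))
    axial_extension(conf_coords(rel$config), protocol, axis)
  }, numeric(1))
  k <- unname(stats::coef(stats::lm(tensions ~ ext))[2])
  structure(k, extensions = ext, tensions = tensions)
}

#' Scan bond/angle stiffness against a target stretch stiffness
#'
#' Evaluates [stretch_stiffness()] on a 39-subunit filament over a
#' (k_l, k_theta) grid and selects the point whose measured stiffness is
#' closest to the target (37 pN/nm for the ATP state, 31 pN/nm for ADP).
#'
#' @param k_l_grid,k_theta_grid stiffness grids (pN/nm, pN nm/rad^2).
#' @param target target stretch stiffness, pN/nm.
#' @param k_phi dihedral constant held fixed during the scan (the stretch
#'   response is insensitive to it), pN nm.
#' @param n_subunits filament size (default 39).
#' @param tensions tension series, pN.
#' @return a `stiffness_scan`: list with `grid` (data frame k_l, k_theta,
#'   stiffness), `selected` ([mechanical_params()]), `measured` (pN/nm at
#'   the selected point) and `target`.
#' @export
scan_stiffness <- function(k_l_grid, k_theta_grid, target,
                           k_phi = 100, n_subunits = 39L,
                           tensions = c(0, 10, 20)) {
  if (!length(k_l_grid) || !length(k_theta_grid)) stop("empty grid")
  config <- build_canonical_lattice(lattice_params(n_subunits = n_subunits))
  topo <- derive_topology(config)
  grid <- expand.grid(k_l = k_l_grid, k_theta = k_theta_grid)
  grid$stiffness <- NA_real_
  for (q in seq_len(nrow(grid))) {
    mech <- mechanical_params(grid$k_l[q], grid$k_theta[q], k_phi)
    grid$stiffness[q] <- as.numeric(
      stretch_stiffness(topo, mech, tensions, config = config))
  }
  if (all(!is.finite(grid$stiffness))) stop("no grid point converged")
  best <- which.min(abs(grid$stiffness - target))
  structure(list(grid = grid,
                 selected = mechanical_params(grid$k_l[best],
                                              grid$k_theta[best], k_phi),
                 measured = grid$stiffness[best],
                 target = target),
            class = "stiffness_scan")
}

#' @export
print.stiffness_scan <- function(x, ...) {
  cat(sprintf("Stiffness scan: %d points, target %.1f pN/nm\n",
              nrow(x$grid), x$target))
  cat(sprintf("  selected k_l = %.3g pN/nm, k_theta = %.3g pN nm/rad^2 -> %.2f pN/nm\n",
              x$selected$k_l, x$selected$k_theta, x$measured))
  invisible(x)
}

#' Per-subunit twist variance profile of a thermal trajectory
#'
#' For every frame, measures per-interface twist and subtracts the
#' canonical twist; the per-subunit variance is the zero-mean maximum
#' likelihood estimate (mean of squared deviations). Terminal subunits
#' are excluded to avoid edge effects, and the cumulative variance is
#' accumulated along subunit index.
#'
#' @param traj a `cg_trajectory` (or list with a `frames` array) of a
#'   thermal run.
#' @param canonical_twist reference twist, degrees.
#' @param exclude_terminal subunits dropped at each end (default 20).
#' @return a `twist_variance_profile`: list with `subunit` (0-based index),
#'   `variance` (deg^2), `cumulative` (deg^2) and `n_frames`.
#' @export
twist_variance_profile <- function(traj, canonical_twist = -166.67,
                                   exclude_terminal = 20L) {
  frames <- traj$frames
  nf <- dim(frames)[3]
  if (nf < 2) stop("need at least 2 frames for variance statistics")
  n <- dim(frames)[1]
  if (n < 2 * exclude_terminal + 2)
    stop("filament too short for the requested terminal exclusion")
  keep <- (exclude_terminal + 1):(n - exclude_terminal)  # 1-based interface rows
  dev2 <- matrix(0, length(keep), nf)
  for (f in seq_len(nf)) {
    tw <- measure_subunit_twist(frames[, , f])
    dev2[, f] <- (tw[keep] - canonical_twist)^2
  }
  v <- rowMeans(dev2)
  structure(list(subunit = keep - 1L, variance = v, cumulative = cumsum(v),
                 n_frames = nf, exclude_terminal = exclude_terminal),
            class = "twist_variance_profile")
}

#' @export
print.twist_variance_profile <- function(x, ...) {
  cat(sprintf("Twist variance profile: %d subunits over %d frames, mean %.2f deg^2\n",
              length(x$variance), x$n_frames, mean(x$variance)))
  invisible(x)
}

#' Simulate a thermal run and return its cumulative twist variance
#'
#' Convenience wrapper used both to generate reference curves and inside
#' [scan_twist_stiffness()]: simulates thermal fluctuations of an
#' `n_subunits` filament under the Langevin thermostat and computes the
#' cumulative twist variance profile.
#'
#' @param mech [mechanical_params()].
#' @param n_subunits filament size (default 100).
#' @param integ [integrator_params()]; the seed is used as given so scans
#'   share common random numbers.
#' @param discard fraction of initial frames discarded as equilibration.
#' @param exclude_terminal passed to [twist_variance_profile()].
#' @return a `twist_variance_profile`.
#' @export
thermal_twist_profile <- function(mech, n_subunits = 100L,
                                  integ = integrator_params(),
                                  discard = 0.2, exclude_terminal = 20L) {
  params <- lattice_params(n_subunits = n_subunits)
  config <- build_canonical_lattice(params)
  topo <- derive_topology(config)
  protocol <- force_protocol("constant", "tension", per_particle_force = 0,
                             n_fixed = 0L, n_loaded = 1L)
  traj <- run_dynamics(config, topo, mech, protocol, integ)
  nf <- dim(traj$frames)[3]
  keep <- seq(floor(discard * nf) + 1, nf)
  traj$frames <- traj$frames[, , keep, drop = FALSE]
  twist_variance_profile(traj, canonical_twist = params$twist,
                         exclude_terminal = exclude_terminal)
}

#' Scan dihedral/angle stiffness against a twist-variance reference
#'
#' Simulates thermal fluctuations of a 100-subunit filament at each
#' (k_phi, k_theta) grid point and selects the pair whose cumulative
#' twist-variance curve is closest (least squares) to the reference curve.
#' All grid points share the reference's integrator seed so that the
#' comparison uses common random numbers.
#'
#' @param k_phi_grid dihedral stiffness grid, pN nm.
#' @param k_theta_grid angle stiffness refinement grid, pN nm/rad^2.
#' @param reference a `twist_variance_profile` (e.g. simulator-generated)
#'   or a numeric cumulative-variance vector.
#' @param k_l bond stiffness held fixed, pN/nm.
#' @param n_subunits,integ,discard,exclude_terminal simulation settings,
#'   which must match how the reference was generated.
#' @return list with `grid` (data frame k_phi, k_theta, distance),
#'   `selected` ([mechanical_params()]) and `curves`.
#' @export
scan_twist_stiffness <- function(k_phi_grid, k_theta_grid, reference, k_l,
                                 n_subunits = 100L,
                                 integ = integrator_params(),
                                 discard = 0.2, exclude_terminal = 20L) {
  ref <- if (inherits(reference, "twist_variance_profile"))
    reference$cumulative else as.numeric(reference)
  if (!length(ref)) stop("empty reference curve")
  if (!length(k_phi_grid) || !length(k_theta_grid)) stop("empty grid")
  grid <- expand.grid(k_phi = k_phi_grid, k_theta = k_theta_grid)
  grid$distance <- NA_real_
  curves <- vector("list", nrow(grid))
  for (q in seq_len(nrow(grid))) {
    mech <- mechanical_params(k_l, grid$k_theta[q], grid$k_phi[q])
    prof <- thermal_twist_profile(mech, n_subunits, integ,
                                  discard, exclude_terminal)
    if (length(prof$cumulative) != length(ref))
      stop("reference length does not match simulated profile length")
    grid$distance[q] <- sum((prof$cumulative - ref)^2)
    curves[[q]] <- prof$cumulative
  }
  best <- which.min(grid$distance)
  list(grid = grid,
       selected = mechanical_params(k_l, grid$k_theta[best], grid$k_phi[best]),
       curves = curves)
}
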
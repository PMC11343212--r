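# Synthetic-data generators. Every generator is a pure function of its
# parameters and a mandatory seed, and attaches a machine-readable ground
# truth record, so each analysis stage can be tested as a generator ->
# analyzer round trip without external data.

rot_y <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
}

#' Generate a superhelical filament trace with known ground truth
#'
#' Marker points on an ideal superhelix about a straight axis:
#' transverse coordinates A2 sin(2 pi t / lambda) and A3 cos(2 pi t / lambda)
#' at axial position t, plus optional isotropic Gaussian marker noise
#' (default 1 nm, the scale of manual tracing jitter). Setting `amp3 = 0`
#' gives a planar sinusoid fixture. The ideal construction has a
#' quarter-wavelength phase offset between the two transverse planes.
#'
#' @param wavelength_nm superhelix wavelength (default 160 nm).
#' @param amp2,amp3 transverse amplitudes, nm.
#' @param length_nm axial length of the trace.
#' @param marker_step_nm marker spacing (5 nm, manual-pick scale).
#' @param noise_sd_nm isotropic marker noise.
#' @param tilt_deg rigid rotation of the whole trace about the minor-axis
#'   direction, tilting the major axis out of the z = 0 plane by this angle.
#' @param seed RNG seed (mandatory).
#' @return list with `markers` (m x 3, nm), `truth` (wavelength, amplitudes,
#'   phase offset 0.25, tilt) and `noiseless` points.
#' @export
gen_superhelix_trace <- function(wavelength_nm = 160, amp2 = 10, amp3 = 10,
                                 length_nm = 500, marker_step_nm = 5,
                                 noise_sd_nm = 1, tilt_deg = 0, seed) {
  if (wavelength_nm <= 0) stop("wavelength must be > 0")
  set.seed(seed)
  t <- seq(0, length_nm, by = marker_step_nm)
  pts <- cbind(amp2 * sin(2 * pi * t / wavelength_nm),
               amp3 * cos(2 * pi * t / wavelength_nm),
               t)
  if (tilt_deg != 0) pts <- pts %*% t(rot_y(tilt_deg))
  markers <- pts + matrix(stats::rnorm(length(pts), sd = noise_sd_nm), ncol = 3)
  list(markers = markers, noiseless = pts,
       truth = list(wavelength_nm = wavelength_nm, amp2 = amp2, amp3 = amp3,
                    phase_offset = 0.25, tilt_deg = tilt_deg,
                    noise_sd_nm = noise_sd_nm, seed = seed))
}

#' Generate ice-plane marker points at a programmed angle to a trace
#'
#' Points on a plane that contains the z axis (the untilted superhelix
#' trace axis, so the filament lies in-plane as in a thin ice layer) and
#' whose angle to the x axis (the trace's major transverse direction) is
#' `angle_deg`. Used to test the major-axis-versus-ice-plane angle
#' measurement.
#'
#' @param angle_deg programmed angle between the plane and the x axis.
#' @param n number of points.
#' @param extent_nm half-extent of the sampled patch.
#' @param noise_sd_nm out-of-plane jitter.
#' @param seed RNG seed.
#' @return n x 3 matrix of plane points (nm), with the plane normal as
#'   attribute `normal`.
#' @export
gen_plane_points <- function(angle_deg = 30, n = 50, extent_nm = 500,
                             noise_sd_nm = 0.5, seed) {
  set.seed(seed)
  th <- angle_deg * pi / 180
  nrm <- c(sin(th), cos(th), 0)
  v1 <- c(0, 0, 1)
  v2 <- c(cos(th), -sin(th), 0)
  a <- stats::runif(n, -extent_nm, extent_nm)
  b <- stats::runif(n, -extent_nm, extent_nm)
  pts <- outer(a, v1) + outer(b, v2) +
    outer(stats::rnorm(n, sd = noise_sd_nm), nrm)
  attr(pts, "normal") <- nrm
  pts
}

#' Generate a planar circular-arc filament trace
#'
#' @param curvature_um unsigned arc curvature, 1/um.
#' @param length_nm arc length.
#' @param marker_step_nm,noise_sd_nm,seed as in [gen_superhelix_trace()].
#' @return list with `markers`, `noiseless`, `truth`.
#' @export
gen_planar_arc_trace <- function(curvature_um = 2, length_nm = 500,
                                 marker_step_nm = 5, noise_sd_nm = 1, seed) {
  if (curvature_um <= 0) stop("curvature must be > 0")
  set.seed(seed)
  R <- 1000 / curvature_um               # nm
  s <- seq(0, length_nm, by = marker_step_nm)
  th <- s / R
  pts <- cbind(R * sin(th), R * (1 - cos(th)), rep(0, length(s)))
  markers <- pts + matrix(stats::rnorm(length(pts), sd = noise_sd_nm), ncol = 3)
  list(markers = markers, noiseless = pts,
       truth = list(curvature_um = curvature_um, torsion_um = 0, seed = seed))
}

#' Generate a straight filament trace
#' @inheritParams gen_planar_arc_trace
#' @return list with `markers`, `noiseless`, `truth`.
#' @export
gen_straight_trace <- function(length_nm = 500, marker_step_nm = 5,
                               noise_sd_nm = 1, seed) {
  set.seed(seed)
  s <- seq(0, length_nm, by = marker_step_nm)
  pts <- cbind(s, rep(0, length(s)), rep(0, length(s)))
  markers <- pts + matrix(stats::rnorm(length(pts), sd = noise_sd_nm), ncol = 3)
  list(markers = markers, noiseless = pts,
       truth = list(curvature_um = 0, seed = seed))
}

#' Generate a lattice with programmed per-interface rise/twist modulation
#'
#' Builds the filament subunit by subunit: interface i applies a twist of
#' `twist + twist_mod(i)` degrees and a rise of `rise + rise_mod(i)`
#' Angstrom about the (optionally offset) axis, emulating wavelike
#' over/under-twisting and over/under-extension patterns with exact
#' ground truth.
#'
#' @param params [lattice_params()].
#' @param rise_mod,twist_mod functions of the 0-based interface index
#'   returning the modulation in Angstrom / degrees (`NULL` = none).
#' @param axis_offset optional function of axial position z (nm) returning
#'   a transverse offset `c(dx, dy)` in nm (a superhelical axis path).
#' @return list with `config` ([filament_conf()]), `truth` (per-interface
#'   `rise_A` and `twist_deg` programs).
#' @export
gen_modulated_lattice <- function(params = lattice_params(),
                                  rise_mod = NULL, twist_mod = NULL,
                                  axis_offset = NULL) {
  n <- params$n_subunits
  i <- seq_len(n - 1) - 1
  rise_i <- rep(params$rise, n - 1) + if (is.null(rise_mod)) 0 else
    vapply(i, rise_mod, numeric(1))
  twist_i <- rep(params$twist, n - 1) + if (is.null(twist_mod)) 0 else
    vapply(i, twist_mod, numeric(1))
  if (any(rise_i <= 0)) stop("modulation produced non-positive rise")
  ang <- cumsum(c(0, twist_i)) * pi / 180
  z <- cumsum(c(0, rise_i)) / 10
  r_nm <- params$radius / 10
  pos <- cbind(r_nm * cos(ang), r_nm * sin(ang), z)
  if (!is.null(axis_offset)) {
    off <- t(vapply(z, axis_offset, numeric(2)))
    pos[, 1] <- pos[, 1] + off[, 1]
    pos[, 2] <- pos[, 2] + off[, 2]
  }
  list(config = filament_conf(pos),
       truth = list(rise_A = rise_i, twist_deg = twist_i))
}

#' Generate a trajectory with i.i.d. Gaussian twist noise
#'
#' Each frame is a canonical lattice whose per-interface twist carries
#' independent zero-mean Gaussian noise of the given standard deviation,
#' giving an exact per-subunit twist variance of sigma^2 for testing the
#' variance profile machinery.
#'
#' @param params [lattice_params()].
#' @param sigma_deg twist noise s.d., degrees.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return list mimicking a trajectory (`frames` array) plus `truth`.
#' @export
gen_twist_noise_trajectory <- function(params = lattice_params(),
                                       sigma_deg = 2, n_frames = 100, seed) {
  set.seed(seed)
  n <- params$n_subunits
  frames <- array(0, dim = c(n, 3, n_frames))
  for (f in seq_len(n_frames)) {
    noise <- stats::rnorm(n - 1, sd = sigma_deg)
    g <- gen_modulated_lattice(params,
                               twist_mod = function(i) noise[i + 1])
    frames[, , f] <- conf_coords(g$config)
  }
  list(frames = frames,
       truth = list(sigma_deg = sigma_deg, variance_deg2 = sigma_deg^2,
                    seed = seed))
}

# curvature program helpers for synthetic segmentation images -------------

#' Filament path specifications for synthetic segmentation maps
#'
#' `seg_straight`, `seg_arc` and `seg_s` describe filament centre-lines by
#' their signed curvature along arc length; `seg_s` is an S-shaped
#' filament made of two arcs of opposite sign (the minimal superhelical
#' projection).
#'
#' @param length_px path length, px.
#' @param curvature_um arc curvature magnitude, 1/um.
#' @param start c(row, col) start pixel.
#' @param direction_deg initial heading, degrees (0 = along +col).
#' @return a path spec list.
#' @export
seg_straight <- function(length_px = 600, start = c(100, 50), direction_deg = 0) {
  list(kind = "straight", curvature = function(s) 0, length_px = length_px,
       start = start, direction_deg = direction_deg, superhelical = FALSE)
}

#' @rdname seg_straight
#' @export
seg_arc <- function(curvature_um = 2, length_px = 600, start = c(100, 50),
                    direction_deg = 0) {
  k <- curvature_um
  list(kind = "arc", curvature = function(s) k, length_px = length_px,
       start = start, direction_deg = direction_deg, superhelical = FALSE)
}

#' @rdname seg_straight
#' @param run_px arc length of each constant-sign lobe, px.
#' @export
seg_s <- function(curvature_um = 2, run_px = 300, length_px = 2 * run_px,
                  start = c(100, 50), direction_deg = 0) {
  k <- curvature_um
  list(kind = "s_curve",
       curvature = function(s) ifelse(s < run_px, k, -k),
       length_px = length_px, start = start, direction_deg = direction_deg,
       superhelical = NA) # decided against thresholds at generation time
}

trace_path_px <- function(spec, apix) {
  s <- seq(0, spec$length_px - 1)
  th <- spec$direction_deg * pi / 180
  kappa_px <- vapply(s, spec$curvature, numeric(1)) * apix / 1e4
  heading <- th + cumsum(c(0, kappa_px[-length(kappa_px)]))
  dr <- sin(heading); dc <- cos(heading)
  cbind(spec$start[1] + cumsum(c(0, dr[-length(dr)])),
        spec$start[2] + cumsum(c(0, dc[-length(dc)])))
}

#' Generate a synthetic segmentation map with ground-truth picks
#'
#' Rasterises filament centre-line programs with a Gaussian cross-section
#' profile (so the standard 0.3 binarisation threshold is meaningful) and
#' records, per filament, whether its curvature program satisfies the
#' dual-sign superhelix criterion.
#'
#' @param specs list of path specs ([seg_straight()], [seg_arc()],
#'   [seg_s()]).
#' @param nrow_px,ncol_px canvas size.
#' @param apix pixel size, Angstrom.
#' @param width_sigma_px Gaussian cross-section sigma, px.
#' @param noise_sd additive Gaussian pixel noise (clipped to [0, 1]).
#' @param seed RNG seed.
#' @param kappa_thr,min_run criterion used to label ground truth.
#' @return list with `map` ([segmentation_map()]), `truth` (data frame:
#'   filament, kind, superhelical) and `paths` (centre-lines, px).
#' @export
gen_segmentation_image <- function(specs, nrow_px = 768, ncol_px = 768,
                                   apix = 4.32, width_sigma_px = 4,
                                   noise_sd = 0, seed = 1,
                                   kappa_thr = 1.5, min_run = 200) {
  set.seed(seed)
  paths <- lapply(specs, trace_path_px, apix = apix)
  clipped <- FALSE
  for (q in seq_along(paths)) {
    p <- paths[[q]]
    ok <- p[, 1] >= 1 & p[, 1] <= nrow_px & p[, 2] >= 1 & p[, 2] <= ncol_px
    if (!all(ok)) { clipped <- TRUE; paths[[q]] <- p[ok, , drop = FALSE] }
  }
  if (clipped) warning("some paths were clipped to the canvas")
  allpts <- do.call(rbind, paths)
  img <- if (is.null(allpts) || !nrow(allpts))
    matrix(0, nrow_px, ncol_px)
  else
    raster_paths_cpp(nrow_px, ncol_px, allpts - 1, width_sigma_px)
  if (noise_sd > 0)
    img <- pmin(1, pmax(0, img + matrix(stats::rnorm(length(img), sd = noise_sd),
                                        nrow_px)))
  truth <- do.call(rbind, lapply(seq_along(specs), function(q) {
    sp <- specs[[q]]
    s <- seq(0, sp$length_px - 1)
    kap <- vapply(s, sp$curvature, numeric(1))
    span <- function(cond) {
      r <- rle(cond)
      if (!any(r$values)) return(0)
      max(r$lengths[r$values]) * apix
    }
    flag <- span(kap >= kappa_thr) >= min_run && span(kap <= -kappa_thr) >= min_run
    data.frame(filament = q, kind = sp$kind, superhelical = flag)
  }))
  list(map = segmentation_map(img, apix), truth = truth, paths = paths)
}

#' Sample curvatures from the Boltzmann curvature model
#'
#' i.i.d. draws from the half-Gaussian with scale 1/sqrt(alpha L_p L),
#' the sampling counterpart of [curvature_pdf()].
#'
#' @param n sample count (> 0).
#' @param L_p,L persistence length and segment length, um.
#' @param alpha adjustment factor.
#' @param seed RNG seed.
#' @return numeric vector of curvatures, 1/um.
#' @export
sample_curvatures <- function(n, L_p, L, alpha = 1, seed) {
  if (n <= 0) stop("n must be > 0")
  set.seed(seed)
  abs(stats::rnorm(n, sd = 1 / sqrt(alpha * L_p * L)))
}

#' Generate a synthetic protomer pair with programmed subdomain shifts
#'
#' Builds a synthetic reference C-alpha model (a smoothed random walk,
#' standing in for a real protomer fold) and a copy in which whole
#' subdomain residue ranges are rigidly shifted by programmed vectors.
#'
#' @param shifts named list: names are subdomain range labels from
#'   [actin_subdomain_scheme()] (e.g. `"35-72"`), values length-3 shift
#'   vectors in Angstrom.
#' @param n_res residue count (375).
#' @param seed RNG seed.
#' @return list with `reference`, `model` ([protomer_model()]s) and
#'   `truth` (the shift list).
#' @export
gen_shifted_protomer <- function(shifts = list(), n_res = 375, seed) {
  set.seed(seed)
  steps <- matrix(stats::rnorm(3 * n_res, sd = 2), ncol = 3)
  xyz <- apply(steps, 2, cumsum)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  resno <- seq_len(n_res)
  reference <- protomer_model(xyz, resno, source = "synthetic")
  scheme <- actin_subdomain_scheme()
  xyz2 <- xyz
  for (nm in names(shifts)) {
    row <- scheme[scheme$name == nm, ]
    if (!nrow(row)) stop("unknown subdomain range: ", nm)
    sel <- resno >= row$start & resno <= row$end
    xyz2[sel, ] <- sweep(xyz2[sel, , drop = FALSE], 2, -as.numeric(shifts[[nm]]))
  }
  list(reference = reference,
       model = protomer_model(xyz2, resno, source = "synthetic-shifted"),
       truth = shifts)
}
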
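#' Total elastic energy of a filament configuration
#'
#' Sums the harmonic bond term 1/2 k_l (l - l0)^2, the harmonic angle term
#' 1/2 k_theta (theta - theta0)^2 and the cosine dihedral term
#' k_phi (1 - cos(n phi - phi0)) over the network. The configuration used
#' to derive the topology has exactly zero energy.
#'
#' @param config a [filament_conf()].
#' @param topo a [derive_topology()] result with matching subunit count.
#' @param mech a [mechanical_params()] object.
#' @return energy in pN nm (scalar, >= 0).
#' @export
total_energy <- function(config, topo, mech) {
  stopifnot(inherits(config, "filament_conf"))
  if (nrow(config) != topo$n_subunits)
    stop("configuration and topology subunit counts differ")
  a <- topo_arrays(topo, mech)
  cg_energy_cpp(conf_coords(config), a$bonds, a$l0, a$kl,
                a$angles, a$th0, a$kth,
                a$dihedrals, a$ph0, a$kph, a$mult)
}

#' Per-particle elastic forces
#'
#' Analytic negative gradient of [total_energy()] with respect to particle
#' positions. Internal forces sum to zero and exert zero net torque.
#'
#' @inheritParams total_energy
#' @return n x 3 matrix of forces in pN, with the configuration's energy
#'   attached as attribute `"energy"`.
#' @export
compute_forces <- function(config, topo, mech) {
  stopifnot(inherits(config, "filament_conf"))
  if (nrow(config) != topo$n_subunits)
    stop("configuration and topology subunit counts differ")
  a <- topo_arrays(topo, mech)
  cg_forces_cpp(conf_coords(config), a$bonds, a$l0, a$kl,
                a$angles, a$th0, a$kth,
                a$dihedrals, a$ph0, a$kph, a$mult)
}
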
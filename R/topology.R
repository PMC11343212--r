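#' Mechanical spring constants of the filament network
#'
#' @param k_l harmonic bond stiffness, pN/nm. A single constant is shared by
#'   lateral and axial bonds; `k_l_axial` overrides it for axial bonds.
#' @param k_theta harmonic angle stiffness, pN nm / rad^2.
#' @param k_phi dihedral stiffness, pN nm.
#' @param k_l_axial optional axial-bond override of `k_l`.
#' @return a `mechanical_params` object.
#' @export
mechanical_params <- function(k_l, k_theta, k_phi, k_l_axial = k_l) {
  vals <- c(k_l = k_l, k_theta = k_theta, k_phi = k_phi, k_l_axial = k_l_axial)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all stiffness constants must be finite and > 0")
  structure(as.list(vals), class = "mechanical_params")
}

#' @export
print.mechanical_params <- function(x, ...) {
  cat(sprintf("Mechanical parameters: k_l %.3g pN/nm, k_theta %.3g pN nm/rad^2, k_phi %.3g pN nm\n",
              x$k_l, x$k_theta, x$k_phi))
  invisible(x)
}

angle_at <- function(pos, j, i, k) {
  u <- pos[j, ] - pos[i, ]
  v <- pos[k, ] - pos[i, ]
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, ct)))
}

dihedral_at <- function(pos, i, j, k, l) {
  b1 <- pos[j, ] - pos[i, ]
  b2 <- pos[k, ] - pos[j, ]
  b3 <- pos[l, ] - pos[k, ]
  n1 <- c(b1[2]*b2[3] - b1[3]*b2[2], b1[3]*b2[1] - b1[1]*b2[3], b1[1]*b2[2] - b1[2]*b2[1])
  n2 <- c(b2[2]*b3[3] - b2[3]*b3[2], b2[3]*b3[1] - b2[1]*b3[3], b2[1]*b3[2] - b2[2]*b3[1])
  m1 <- c(n1[2]*n2[3] - n1[3]*n2[2], n1[3]*n2[1] - n1[1]*n2[3], n1[1]*n2[2] - n1[2]*n2[1])
  atan2(sum(m1 * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

#' Derive the spring-network topology from an equilibrium configuration
#'
#' Each subunit bonds to its genetic-helix neighbour (i, i+1; "lateral"
#' cross-strand contact) and to the next subunit along its own long-pitch
#' strand (i, i+2; "axial" contact). Every interior particle is the vertex
#' of the six angle triplets formed by choosing two of its four bonded
#' neighbours {i-2, i-1, i+1, i+2}, and leads two dihedral quadruplets, one
#' along the genetic helix (i, i+1, i+2, i+3) and one along its long-pitch
#' strand (i, i+2, i+4, i+6). All rest values (l0, theta0, phi0) are
#' measured on the input configuration, which is therefore the exact
#' zero-energy state of the derived network.
#'
#' @param config a [filament_conf()] with at least 7 subunits.
#' @return a `spring_topology`: list of data frames `bonds`
#'   (i, j, type, l0 in nm), `angles` (j, i, k, theta0 in rad) and
#'   `dihedrals` (i, j, k, l, phi0 in rad, n). Indices are 0-based.
#' @export
derive_topology <- function(config) {
  stopifnot(inherits(config, "filament_conf"))
  n <- nrow(config)
  if (n < 7) stop("topology requires at least 7 subunits")
  pos <- conf_coords(config)

  i1 <- seq_len(n - 1)                      # 1-based row of first member
  lat <- cbind(i1, i1 + 1)
  i2 <- seq_len(n - 2)
  axi <- cbind(i2, i2 + 2)
  blen <- function(idx) sqrt(rowSums((pos[idx[, 1], , drop = FALSE] -
                                      pos[idx[, 2], , drop = FALSE])^2))
  bonds <- data.frame(
    i = c(lat[, 1], axi[, 1]) - 1L,
    j = c(lat[, 2], axi[, 2]) - 1L,
    type = rep(c("lateral", "axial"), c(nrow(lat), nrow(axi))),
    l0 = c(blen(lat), blen(axi)),
    stringsAsFactors = FALSE)

  # angles: vertex i (1-based rows 3..n-2), arms = pairs of bonded neighbours
  arm_offsets <- utils::combn(c(-2L, -1L, 1L, 2L), 2)
  verts <- 3:(n - 2)
  ang <- do.call(rbind, lapply(seq_len(ncol(arm_offsets)), function(q) {
    cbind(j = verts + arm_offsets[1, q], i = verts, k = verts + arm_offsets[2, q])
  }))
  ang <- ang[order(ang[, "i"], ang[, "j"], ang[, "k"]), , drop = FALSE]
  theta0 <- vapply(seq_len(nrow(ang)), function(q)
    angle_at(pos, ang[q, 1], ang[q, 2], ang[q, 3]), numeric(1))
  angles <- data.frame(j = ang[, 1] - 1L, i = ang[, 2] - 1L, k = ang[, 3] - 1L,
                       theta0 = theta0)

  dih <- rbind(
    do.call(rbind, lapply(seq_len(n - 3), function(q) q + 0:3)),       # genetic
    do.call(rbind, lapply(seq_len(n - 6), function(q) q + c(0, 2, 4, 6)))) # strand
  phi0 <- vapply(seq_len(nrow(dih)), function(q)
    dihedral_at(pos, dih[q, 1], dih[q, 2], dih[q, 3], dih[q, 4]), numeric(1))
  dihedrals <- data.frame(i = dih[, 1] - 1L, j = dih[, 2] - 1L,
                          k = dih[, 3] - 1L, l = dih[, 4] - 1L,
                          phi0 = phi0, n = 1L)

  structure(list(bonds = bonds, angles = angles, dihedrals = dihedrals,
                 n_subunits = n),
            class = "spring_topology")
}

#' @export
print.spring_topology <- function(x, ...) {
  cat(sprintf("Spring topology: %d subunits, %d bonds, %d angles, %d dihedrals\n",
              x$n_subunits, nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals)))
  invisible(x)
}

# Flatten a topology + mechanical params into the argument set of the C++
# kernels. Returns a list of matrices/vectors with 0-based indices.
topo_arrays <- function(topo, mech) {
  stopifnot(inherits(topo, "spring_topology"), inherits(mech, "mechanical_params"))
  kl <- ifelse(topo$bonds$type == "axial", mech$k_l_axial, mech$k_l)
  list(
    bonds = cbind(topo$bonds$i, topo$bonds$j),
    l0 = topo$bonds$l0, kl = kl,
    angles = cbind(topo$angles$j, topo$angles$i, topo$angles$k),
    th0 = topo$angles$theta0,
    kth = rep(mech$k_theta, nrow(topo$angles)),
    dihedrals = cbind(topo$dihedrals$i, topo$dihedrals$j,
                      topo$dihedrals$k, topo$dihedrals$l),
    ph0 = topo$dihedrals$phi0,
    kph = rep(mech$k_phi, nrow(topo$dihedrals)),
    mult = as.integer(topo$dihedrals$n))
}
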
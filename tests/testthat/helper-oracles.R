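# Independent oracles used across the suite. These re-derive quantities by
# routes separate from the package implementation (literal term-by-term
# energy transcription, finite differences, exhaustive search) so that
# implementation and check never share code.

# Literal transcription of the three potentials:
# V(l) = 1/2 k_l (l - l0)^2, V(th) = 1/2 k_th (th - th0)^2,
# V(phi) = k_phi (1 - cos(n phi - phi0)); summed term by term in R.
oracle_energy <- function(pos, topo, mech) {
  E <- 0
  for (q in seq_len(nrow(topo$bonds))) {
    b <- topo$bonds[q, ]
    l <- sqrt(sum((pos[b$i + 1, ] - pos[b$j + 1, ])^2))
    kl <- if (b$type == "axial") mech$k_l_axial else mech$k_l
    E <- E + 0.5 * kl * (l - b$l0)^2
  }
  for (q in seq_len(nrow(topo$angles))) {
    a <- topo$angles[q, ]
    u <- pos[a$j + 1, ] - pos[a$i + 1, ]
    v <- pos[a$k + 1, ] - pos[a$i + 1, ]
    th <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    E <- E + 0.5 * mech$k_theta * (th - a$theta0)^2
  }
  for (q in seq_len(nrow(topo$dihedrals))) {
    d <- topo$dihedrals[q, ]
    p1 <- pos[d$i + 1, ]; p2 <- pos[d$j + 1, ]
    p3 <- pos[d$k + 1, ]; p4 <- pos[d$l + 1, ]
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
            n1[1] * n2[2] - n1[2] * n2[1])
    phi <- atan2(sum(m1 * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
    E <- E + mech$k_phi * (1 - cos(d$n * phi - d$phi0))
  }
  E
}

# central finite-difference gradient of total_energy
oracle_fd_forces <- function(config, topo, mech, h = 1e-6) {
  pos <- conf_coords(config)
  f <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) for (c in 1:3) {
    pp <- pos; pp[i, c] <- pp[i, c] + h
    pm <- pos; pm[i, c] <- pm[i, c] - h
    f[i, c] <- -(total_energy(filament_conf(pp), topo, mech) -
                   total_energy(filament_conf(pm), topo, mech)) / (2 * h)
  }
  f
}

# one-sample KS statistic by direct supremum over the empirical CDF
oracle_ks_D <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(pmax(abs(Fx - (seq_len(n) - 1) / n), abs(seq_len(n) / n - Fx)))
}

# exhaustive greedy-from-first NMS reference: among all subsets containing
# the first pick with pairwise separation >= min_sep, the greedy solution
# is the one produced by scanning in order; enumerate to verify maximality
oracle_nms_exhaustive <- function(positions, min_sep) {
  n <- length(positions)
  best <- NULL
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!length(sel) || sel[1] != 1) next
    p <- positions[sel]
    if (length(p) > 1 && any(diff(p) < min_sep)) next
    if (is.null(best) || length(sel) > length(best) ||
        (length(sel) == length(best) && sum(positions[sel]) < sum(positions[best])))
      best <- sel
  }
  positions[best]
}

rigid_transform <- function(pts, axis = c(0, 0, 1), angle = 0.7,
                            shift = c(10, -5, 3)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(as.matrix(pts) %*% t(R), 2, shift, "+")
}

canonical_fixture <- function(n = 40) {
  conf <- build_canonical_lattice(lattice_params(n_subunits = n))
  list(conf = conf, topo = derive_topology(conf),
       mech = mechanical_params(100, 50, 80))
}
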
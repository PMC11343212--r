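#' Worm-like-chain bending energy of a curved filament segment
#'
#' E = 1/2 k_B T L_p L kappa^2 : the energy (in units of k_B T) to hold a
#' segment of length L at curvature kappa, for a polymer of persistence
#' length L_p.
#'
#' @param kappa curvature, 1/um (>= 0, vectorised).
#' @param L_p persistence length, um.
#' @param L segment length, um.
#' @return energy in units of k_B T.
#' @export
bending_energy <- function(kappa, L_p, L) {
  if (L_p <= 0 || L <= 0) stop("L_p and L must be > 0")
  if (any(kappa < 0)) stop("kappa must be >= 0")
  0.5 * L_p * L * kappa^2
}

#' Boltzmann curvature distribution on a discrete grid
#'
#' P(kappa) is proportional to exp(-alpha L_p L kappa^2 / 2), normalised so
#' the grid probabilities sum to 1. alpha is a multiplicative adjustment
#' factor acting as a proxy for a differing persistence length; alpha = 1
#' recovers the bare worm-like-chain Boltzmann weight. The exponent is
#' negative by construction (the distribution decays with bending energy).
#'
#' @param L_p,L persistence length and segment length, um.
#' @param alpha adjustment factor (> 0).
#' @param kappa_grid non-negative curvature grid, 1/um.
#' @return numeric vector of probabilities over `kappa_grid` (sums to 1).
#' @export
curvature_pdf <- function(L_p, L, alpha = 1,
                          kappa_grid = seq(0, 20, by = 0.05)) {
  if (!length(kappa_grid)) stop("empty curvature grid")
  if (alpha <= 0) stop("alpha must be > 0")
  if (any(kappa_grid < 0) || is.unsorted(kappa_grid))
    stop("kappa_grid must be sorted and non-negative")
  w <- exp(-alpha * bending_energy(kappa_grid, L_p, L))
  w / sum(w)
}

#' Continuous half-Gaussian density of the curvature model
#'
#' Analytic continuous-normalisation counterpart of [curvature_pdf()],
#' used for cross-checks: the half-normal density with scale
#' 1/sqrt(alpha L_p L) on kappa >= 0.
#'
#' @inheritParams curvature_pdf
#' @param kappa curvature values, 1/um.
#' @return density values.
#' @export
curvature_density <- function(kappa, L_p, L, alpha = 1) {
  s2 <- 1 / (alpha * L_p * L)
  2 * stats::dnorm(kappa, mean = 0, sd = sqrt(s2)) * (kappa >= 0)
}

#' Fit the curvature-model adjustment factor alpha
#'
#' Maximum-likelihood fit of alpha in the half-Gaussian curvature family:
#' the closed form is alpha = 1 / (L_p L mean(kappa^2)).
#'
#' @param samples observed curvatures, 1/um (>= 30 values).
#' @param L_p,L persistence length and segment length, um.
#' @return list with `alpha`, `loglik` and `n`.
#' @export
fit_alpha <- function(samples, L_p, L) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 30) stop("need at least 30 curvature samples")
  m2 <- mean(samples^2)
  if (m2 <= 0) stop("all-zero curvature samples: alpha diverges, fit failed")
  alpha <- 1 / (L_p * L * m2)
  ll <- sum(log(curvature_density(abs(samples), L_p, L, alpha)))
  list(alpha = alpha, loglik = ll, n = length(samples))
}
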
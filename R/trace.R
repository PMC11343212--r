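# Smoothing spline with a scipy-style smoothing factor: the penalty is
# chosen (by bisection on log lambda) so the residual sum of squares
# matches the smoothing factor s. s at or above the straight-line RSS
# returns the least-squares line.
spline_with_rss <- function(t, y, s) {
  lin <- stats::lm(y ~ t)
  if (s <= 0) {
    f <- stats::splinefun(t, y, method = "natural")
    return(f)
  }
  if (sum(stats::resid(lin)^2) <= s) {
    cf <- stats::coef(lin)
    return(function(tt) cf[1] + cf[2] * tt)
  }
  rss_at <- function(loglam) {
    fit <- stats::smooth.spline(t, y, lambda = 10^loglam)
    sum((stats::predict(fit, t)$y - y)^2)
  }
  lo <- -14; hi <- 8
  for (q in 1:60) {
    mid <- (lo + hi) / 2
    if (rss_at(mid) < s) lo <- mid else hi <- mid
  }
  fit <- stats::smooth.spline(t, y, lambda = 10^((lo + hi) / 2))
  function(tt) stats::predict(fit, tt)$y
}

resample_polyline <- function(pts, step) {
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  grid <- seq(0, max(s), by = step)
  out <- sapply(seq_len(ncol(pts)), function(c)
    stats::approx(s, pts[, c], xout = grid)$y)
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  out
}

#' Fit a smooth resampled spline to a 3D filament trace
#'
#' Fits univariate smoothing splines (one per coordinate, against chord
#' arc position) through manually traced marker points with a fixed
#' smoothing factor, then resamples the smooth curve evenly in arc length.
#' Defaults follow tomogram trace processing: smoothing factor 150
#' (a squared-nm residual budget, about 1 nm rms at typical marker
#' counts — the manual-picking jitter scale) and 9.6 Angstrom resampling
#' steps.
#'
#' @param markers m x 3 matrix of marker points (m >= 10). Units per
#'   `units`; duplicate consecutive markers are collapsed.
#' @param smoothing smoothing factor (nm^2 residual bound; 0 interpolates).
#' @param step_A resampling step, Angstrom.
#' @param units `"nm"` or `"angstrom"`.
#' @return a `trace_spline`: list with `points` (k x 3 matrix, nm, evenly
#'   spaced), `step_nm`, `smoothing`, `markers` (nm).
#' @export
fit_trace <- function(markers, smoothing = 150, step_A = 9.6,
                      units = c("nm", "angstrom")) {
  units <- match.arg(units)
  markers <- as.matrix(markers)
  stopifnot(ncol(markers) == 3)
  if (units == "angstrom") markers <- markers / 10
  if (nrow(markers) > 1) {
    dup <- c(FALSE, rowSums(abs(diff(markers))) == 0)
    markers <- markers[!dup, , drop = FALSE]
  }
  if (nrow(markers) < 10) stop("need at least 10 distinct markers")
  t <- c(0, cumsum(sqrt(rowSums(diff(markers)^2))))
  # the smoothing factor bounds the total squared residual in nm^2: 150
  # allows ~1 nm rms at typical marker counts, the manual-jitter scale
  s_nm2 <- smoothing
  fx <- spline_with_rss(t, markers[, 1], s_nm2)
  fy <- spline_with_rss(t, markers[, 2], s_nm2)
  fz <- spline_with_rss(t, markers[, 3], s_nm2)
  fine <- seq(0, max(t), length.out = max(4000L, 10L * nrow(markers)))
  smooth_pts <- cbind(fx(fine), fy(fine), fz(fine))
  pts <- resample_polyline(smooth_pts, step_A / 10)
  structure(list(points = pts, step_nm = step_A / 10, smoothing = smoothing,
                 markers = markers),
            class = "trace_spline")
}

#' @export
print.trace_spline <- function(x, ...) {
  cat(sprintf("Trace spline: %d points at %.3f nm steps (%.1f nm total)\n",
              nrow(x$points), x$step_nm, (nrow(x$points) - 1) * x$step_nm))
  invisible(x)
}

# finite-difference derivatives of an evenly spaced 3D curve
curve_derivs <- function(pts, h) {
  n <- nrow(pts)
  r1 <- (pts[c(2:n, n), ] - pts[c(1, 1:(n - 1)), ]) /
    matrix(c(h, rep(2 * h, n - 2), h), n, 3)
  r2 <- matrix(NA_real_, n, 3)
  r2[2:(n - 1), ] <- (pts[3:n, ] - 2 * pts[2:(n - 1), ] + pts[1:(n - 2), ]) / h^2
  r3 <- matrix(NA_real_, n, 3)
  if (n >= 5)
    r3[3:(n - 2), ] <- (pts[5:n, ] - 2 * pts[4:(n - 1), ] +
                          2 * pts[2:(n - 3), ] - pts[1:(n - 4), ]) / (2 * h^3)
  list(r1 = r1, r2 = r2, r3 = r3)
}

#' Instantaneous curvature and torsion along a trace
#'
#' Curvature kappa = |r' x r''| / |r'|^3 and signed torsion
#' tau = (r' x r'') . r''' / |r' x r''|^2 from derivatives of the evenly
#' resampled curve, in inverse microns.
#'
#' @param trace a [fit_trace()] result (or k x 3 matrix of evenly spaced
#'   points in nm, with `step_nm` attribute or spacing inferred).
#' @return data frame with `s_nm` (arc position), `kappa_um` and `tau_um`;
#'   edge points where derivatives are undefined carry NA.
#' @export
curvature_torsion <- function(trace) {
  if (inherits(trace, "trace_spline")) {
    pts <- trace$points; h <- trace$step_nm
  } else {
    pts <- as.matrix(trace)
    h <- sqrt(sum((pts[2, ] - pts[1, ])^2))
  }
  n <- nrow(pts)
  if (n < 5) stop("need at least 5 points")
  d <- curve_derivs(pts, h)
  sp <- sqrt(rowSums(d$r1^2))
  if (any(sp[2:(n - 1)] < 1e-12)) stop("vanishing speed along trace")
  cr <- cbind(d$r1[, 2] * d$r2[, 3] - d$r1[, 3] * d$r2[, 2],
              d$r1[, 3] * d$r2[, 1] - d$r1[, 1] * d$r2[, 3],
              d$r1[, 1] * d$r2[, 2] - d$r1[, 2] * d$r2[, 1])
  crn <- sqrt(rowSums(cr^2))
  kappa <- crn / sp^3 * 1e3           # nm^-1 -> um^-1
  tau <- rowSums(cr * d$r3) / crn^2 * 1e3
  tau[crn < 1e-12] <- 0
  data.frame(s_nm = (seq_len(n) - 1) * h, kappa_um = kappa, tau_um = tau)
}

# internal: PCA-align one window of evenly spaced points.
# The PCA representation is canonicalised over the proper-rotation /
# traversal ambiguities so that rigidly moved, reversed or re-decomposed
# copies of the same curve align identically: the basis is made
# right-handed, rows are ordered with PC1 increasing, the segment is
# centred on the near-maximal |PC2| peak closest to the midpoint with
# PC2 negative (second derivative positive) there, and of the two
# remaining proper variants the lexicographically smaller PC2 signal is
# kept (the "flip the starting end" convention, made deterministic).
align_segment_points <- function(pts, step, window_nm = 350) {
  n <- nrow(pts)
  p <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  sc <- p$x
  rot <- p$rotation
  if (det(rot) < 0) { sc[, 3] <- -sc[, 3]; rot[, 3] <- -rot[, 3] }
  if (sc[n, 1] < sc[1, 1]) sc <- sc[n:1, , drop = FALSE]

  finish <- function(sc, rot) {
    guard <- max(2L, round(0.1 * n))
    core <- guard:(n - guard)
    if (max(abs(sc[core, 2])) < 1e-6) stop("flat second principal component")
    cand <- core[abs(sc[core, 2]) >= 0.99 * max(abs(sc[core, 2]))]
    imax <- cand[which.min(abs(cand - (n + 1) / 2))]
    if (sc[imax, 2] > 0) {  # rotate pi about PC1
      sc[, 2] <- -sc[, 2]; rot[, 2] <- -rot[, 2]
      sc[, 3] <- -sc[, 3]; rot[, 3] <- -rot[, 3]
    }
    half <- if (is.null(window_nm)) NULL else round(window_nm / 2 / step)
    if (!is.null(half) && n > 2 * half) {
      lo <- min(max(1L, imax - half), n - 2L * half)
      idx <- lo:(lo + 2L * half)
      center <- imax - lo + 1L
    } else {
      idx <- seq_len(n)
      center <- imax
    }
    structure(list(arc = (seq_along(idx) - center) * step,
                   pc1 = sc[idx, 1], pc2 = sc[idx, 2], pc3 = sc[idx, 3],
                   step = step, basis = rot, center3d = p$center),
              class = "oscillatory_segment")
  }

  v1 <- finish(sc, rot)
  # variant B: reverse traversal and rotate pi about PC2
  scB <- sc[n:1, , drop = FALSE]
  scB[, 1] <- -scB[, 1]; scB[, 3] <- -scB[, 3]
  rotB <- rot
  rotB[, 1] <- -rotB[, 1]; rotB[, 3] <- -rotB[, 3]
  v2 <- finish(scB, rotB)
  a <- round(v1$pc2, 9); b <- round(v2$pc2, 9)
  d <- which(a != b)
  if (!length(d) || a[d[1]] < b[d[1]]) v1 else v2
}

#' Identify oscillatory (candidate superhelical) segments of a trace
#'
#' Scans the trace for windows of 350-500 nm whose curvature both exceeds
#' a threshold and oscillates in sign (>= 2 sign changes of the curvature
#' component along the trace's transverse principal direction). This
#' operationalises the visual selection of segments with high, oscillating
#' curvature and torsion.
#'
#' @param trace a [fit_trace()] result.
#' @param min_nm,max_nm segment length bounds (350, 500 nm).
#' @param kappa_thr curvature threshold, 1/um.
#' @param min_sign_changes required sign oscillations.
#' @return list of `oscillatory_segment` windows (possibly empty), each
#'   PCA-decomposed but not yet aligned to a common window.
#' @export
find_oscillatory_segments <- function(trace, min_nm = 350, max_nm = 500,
                                      kappa_thr = 1.5, min_sign_changes = 2L) {
  stopifnot(inherits(trace, "trace_spline"))
  pts <- trace$points
  step <- trace$step_nm
  total <- (nrow(pts) - 1) * step
  if (total < min_nm) return(list())
  win_nm <- min(total, max_nm)
  win <- round(win_nm / step)
  p <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  e2 <- p$rotation[, 2]
  d <- curve_derivs(pts, step)
  sp2 <- rowSums(d$r1^2)
  ksig <- (d$r2 %*% e2) / sp2 * 1e3   # signed transverse curvature, um^-1
  ct <- curvature_torsion(trace)

  segs <- list()
  start <- 1L
  stride <- max(1L, round(25 / step))
  while (start + win <= nrow(pts)) {
    idx <- start:(start + win)
    kmax <- max(ct$kappa_um[idx], na.rm = TRUE)
    kw <- ksig[idx]
    kw <- kw[is.finite(kw) & abs(kw) > 0.1 * kappa_thr]
    flips <- if (length(kw) > 1) sum(diff(sign(kw)) != 0) else 0L
    if (kmax >= kappa_thr && flips >= min_sign_changes) {
      segs[[length(segs) + 1L]] <- pts[idx, , drop = FALSE]
      start <- start + win
    } else {
      start <- start + stride
    }
  }
  lapply(segs, align_segment_points, step = step, window_nm = NULL)
}

#' Align oscillatory segments to a common window
#'
#' Each segment is centred at the maximum-amplitude point of its second
#' principal component with the second derivative positive there,
#' inverted decompositions are flipped, and a common analysis window
#' (350 nm) is imposed.
#'
#' @param segments list of `oscillatory_segment` objects, or of point
#'   matrices (nm, evenly spaced).
#' @param window_nm common window (350 nm).
#' @param step_nm point spacing, used when raw matrices are supplied.
#' @return list of aligned `oscillatory_segment` objects.
#' @export
pca_align <- function(segments, window_nm = 350, step_nm = 0.96) {
  if (!length(segments)) stop("need at least one segment")
  lapply(segments, function(s) {
    if (inherits(s, "oscillatory_segment")) {
      pts <- reconstruct_points(s)
      step <- s$step
    } else {
      pts <- as.matrix(s)
      step <- step_nm
    }
    align_segment_points(pts, step, window_nm = window_nm)
  })
}

reconstruct_points <- function(seg) {
  # rebuild 3D points of a segment from its stored scores (exact)
  sc <- cbind(seg$pc1, seg$pc2, seg$pc3)
  sweep(sc %*% t(seg$basis), 2, seg$center3d, "+")
}

gaussian_blur <- function(y, sigma_samples) {
  if (sigma_samples <= 0) return(y)
  half <- max(1L, ceiling(3 * sigma_samples))
  k <- stats::dnorm(-half:half, sd = sigma_samples)
  k <- k / sum(k)
  n <- length(y)
  ypad <- c(rep(y[1], half), y, rep(y[n], half))
  as.numeric(stats::filter(ypad, k, sides = 2))[(half + 1):(half + n)]
}

first_acf_peak <- function(y, max_lag = length(y) - 3L) {
  n <- length(y)
  y <- y - mean(y)
  # unbiased normalisation so the peak position is not pulled toward
  # smaller lags by the overlap taper
  ac <- vapply(0:max_lag, function(L)
    sum(y[1:(n - L)] * y[(1 + L):n]) / (n - L), numeric(1))
  zero <- which(ac < 0)[1]
  if (is.na(zero)) return(NA_real_)
  q <- zero
  while (q < length(ac) && ac[q + 1] <= ac[q]) q <- q + 1  # descend to minimum
  while (q < length(ac) && ac[q + 1] > ac[q]) q <- q + 1   # climb to first peak
  if (q >= length(ac)) return(NA_real_)
  # parabolic sub-sample refinement around the peak (ties -> smaller lag)
  lag <- q - 1
  if (q > 1 && q < length(ac)) {
    denom <- ac[q - 1] - 2 * ac[q] + ac[q + 1]
    if (denom < 0) lag <- lag + 0.5 * (ac[q - 1] - ac[q + 1]) / denom
  }
  lag
}

#' Spiral statistics of an aligned oscillatory segment
#'
#' Wavelength is the first autocorrelation peak of the PC2 signal after
#' Gaussian smoothing (sigma = 2 nm); amplitudes are the maximum absolute
#' excursions along PC2 and PC3 (the major and minor cross-section axes);
#' the fractional phase offset is the cross-correlation lag between the
#' PC2 and PC3 signals divided by the wavelength, folded into [0, 0.5].
#' Segments with PC2 amplitude below 15 nm are flagged insignificant.
#'
#' @param segment an aligned `oscillatory_segment`.
#' @param blur_sigma_nm Gaussian blur applied before autocorrelation (2 nm).
#' @param amplitude_cutoff_nm significance cutoff (15 nm).
#' @return a `spiral_stats` list: `wavelength_nm`, `amplitude_pc2`,
#'   `amplitude_pc3`, `phase_offset`, `major_nm`, `minor_nm`,
#'   `significant`, `wavelength_defined`, `offset_defined`.
#' @export
spiral_stats <- function(segment, blur_sigma_nm = 2, amplitude_cutoff_nm = 15) {
  stopifnot(inherits(segment, "oscillatory_segment"))
  step <- segment$step
  # the wavelength is defined along PC1 (the filament's long axis), so the
  # transverse signals are regridded evenly in the PC1 coordinate
  o <- order(segment$pc1)
  g1 <- seq(min(segment$pc1), max(segment$pc1), by = step)
  s2 <- stats::approx(segment$pc1[o], segment$pc2[o], xout = g1, ties = mean)$y
  s3 <- stats::approx(segment$pc1[o], segment$pc3[o], xout = g1, ties = mean)$y
  s2 <- gaussian_blur(s2, blur_sigma_nm / step)
  s3 <- gaussian_blur(s3, blur_sigma_nm / step)
  amp2 <- max(abs(segment$pc2))
  amp3 <- max(abs(segment$pc3))
  lag <- first_acf_peak(s2)
  wavelength <- if (is.na(lag)) NA_real_ else lag * step

  offset <- NA_real_
  offset_defined <- FALSE
  if (!is.na(wavelength) && amp3 > max(0.5, 0.02 * amp2)) {
    L <- round(wavelength / step)
    lags <- -L:L
    n <- length(s2)
    cc <- vapply(lags, function(Lq) {
      if (Lq >= 0) sum(s2[1:(n - Lq)] * s3[(1 + Lq):n]) / (n - Lq)
      else sum(s3[1:(n + Lq)] * s2[(1 - Lq):n]) / (n + Lq)
    }, numeric(1))
    b <- which.max(cc)
    best <- lags[b]
    if (b > 1 && b < length(cc)) {  # parabolic sub-sample refinement
      denom <- cc[b - 1] - 2 * cc[b] + cc[b + 1]
      if (denom < 0) best <- best + 0.5 * (cc[b - 1] - cc[b + 1]) / denom
    }
    frac <- (abs(best) * step / wavelength) %% 1
    offset <- min(frac, 1 - frac)
    offset_defined <- TRUE
  }
  structure(list(wavelength_nm = wavelength, amplitude_pc2 = amp2,
                 amplitude_pc3 = amp3, phase_offset = offset,
                 major_nm = amp2, minor_nm = amp3,
                 significant = amp2 >= amplitude_cutoff_nm,
                 wavelength_defined = !is.na(wavelength),
                 offset_defined = offset_defined),
            class = "spiral_stats")
}

#' @export
print.spiral_stats <- function(x, ...) {
  cat(sprintf("Spiral: wavelength %.1f nm, amplitudes %.1f / %.1f nm, offset %s%s\n",
              x$wavelength_nm, x$amplitude_pc2, x$amplitude_pc3,
              if (x$offset_defined) sprintf("%.3f", x$phase_offset) else "undefined",
              if (x$significant) "" else " (insignificant)"))
  invisible(x)
}

#' Angle between a segment's major axis and a fitted plane
#'
#' The plane (e.g. the ice layer, located from marker points in aggregate
#' densities) is fit by PCA: its first two principal components span the
#' plane. The plane's normal is projected orthogonally to the segment's
#' first principal component, and the angle between the segment's second
#' principal component (the major axis of the elliptical cross-section)
#' and the plane is computed from that projected normal.
#'
#' @param segment an `oscillatory_segment` (with 3D basis).
#' @param plane_points m x 3 matrix (>= 3 non-collinear points).
#' @return angle in degrees, in [0, 90].
#' @export
plane_angle <- function(segment, plane_points) {
  stopifnot(inherits(segment, "oscillatory_segment"))
  pp <- as.matrix(plane_points)
  if (nrow(pp) < 3) stop("need at least 3 plane points")
  sv <- svd(sweep(pp, 2, colMeans(pp)))
  if (sv$d[2] / max(sv$d[1], 1e-12) < 1e-8) stop("plane points are collinear")
  nrm <- sv$v[, 3]
  pc1 <- segment$basis[, 1]
  pc2 <- segment$basis[, 2]
  nproj <- nrm - sum(nrm * pc1) * pc1
  npn <- sqrt(sum(nproj^2))
  if (npn < 1e-10) return(0)
  nproj <- nproj / npn
  ang_to_normal <- acos(pmin(1, abs(sum(pc2 * nproj)))) * 180 / pi
  90 - ang_to_normal
}

#' One-sample Kolmogorov-Smirnov test of an angle distribution
#'
#' Tests whether observed major-axis angles differ from a reference
#' distribution (by default a normal distribution fitted to the sample;
#' a standard normal or any CDF callable can be supplied).
#'
#' @param angles numeric sample (>= 3 values).
#' @param reference `"fitted-normal"`, `"standard-normal"`, or a CDF
#'   function.
#' @return list with `D` and `p_value`.
#' @export
ks_uniformity_test <- function(angles, reference = "fitted-normal") {
  if (length(angles) < 3) stop("need at least 3 angles")
  cdf <- if (is.function(reference)) reference
  else if (identical(reference, "fitted-normal"))
    function(q) stats::pnorm(q, mean(angles), stats::sd(angles))
  else if (identical(reference, "standard-normal")) stats::pnorm
  else stop("unknown reference")
  kt <- suppressWarnings(stats::ks.test(angles, cdf))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Spiral statistics of a simulated filament configuration
#'
#' Measures the central-axis path of a configuration, resamples it evenly
#' and applies the PCA alignment and spiral statistics used for traced
#' filaments. Used to quantify wavelength and cross-section of simulated
#' superhelices.
#'
#' @param config a [filament_conf()] (or n x 3 matrix, nm).
#' @param step_nm resampling step.
#' @return a `spiral_stats` object.
#' @export
configuration_spiral_stats <- function(config, step_nm = 0.96) {
  pts <- central_axis_points(conf_coords(as_conf_matrix(config)))
  pts <- resample_polyline(pts, step_nm)
  seg <- align_segment_points(pts, step_nm, window_nm = NULL)
  spiral_stats(seg)
}
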
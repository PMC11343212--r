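#' Fit a variable-radius central-axis spline to subunit centroids
#'
#' Axis points are located by the midpoint construction
#' ([central_axis_points()]), smoothed with a short centred moving average
#' (to remove the sub-Angstrom alternating micro-helix the construction
#' leaves behind), and interpolated with a
#' natural cubic spline reparameterised by arc length. The per-centroid
#' radius is fit separately with a univariate smoothing spline against
#' arc position, so the radius is free to vary along the filament.
#'
#' @param centroids [filament_conf()] or n x 3 matrix (nm), n >= 7.
#' @param smooth_window moving-average window (subunits) applied to the
#'   axis points. The default 5 attenuates the ~2.2-subunit alternation to
#'   below 0.01 nm while passing superhelical wavelengths (>= 100 nm)
#'   essentially unchanged.
#' @param n_dense density of the arc-length resampling used internally.
#' @return an `axis_spline`: list with `at(s)` (axis point, nm),
#'   `tangent(s)` (unit), `radius(s)` (nm), `s_range`, `foot(points)`
#'   (arc positions of orthogonal projections, with linear extension
#'   beyond the fitted domain) and the smoothed axis points.
#' @export
fit_axis_spline <- function(centroids, smooth_window = 5L, n_dense = 4000L) {
  pos <- conf_coords(as_conf_matrix(centroids))
  n <- nrow(pos)
  if (n < 7) stop("need at least 7 centroids")
  m <- central_axis_points(pos)

  # straight-axis branch: when the axis points deviate from their best-fit
  # line by no more than the midpoint construction's residual micro-helix
  # (straight_tol), the axis IS that line, measured exactly
  straight_tol <- 0.2  # nm
  ctr <- colMeans(m)
  mc <- sweep(m, 2, ctr)
  sv <- svd(mc)
  dirv <- sv$v[, 1]
  perp <- sqrt(rowSums((mc - (mc %*% dirv) %*% t(dirv))^2))
  if (max(perp) < straight_tol) {
    # refine the axis direction from the chain's mean screw rotation,
    # which is exact for an unbent helix
    scr <- kabsch(pos[-n, , drop = FALSE], pos[-1, , drop = FALSE])
    w <- c(scr$R[3, 2] - scr$R[2, 3], scr$R[1, 3] - scr$R[3, 1],
           scr$R[2, 1] - scr$R[1, 2])
    if (sqrt(sum(w^2)) > 1e-6) {
      w <- w / sqrt(sum(w^2))
      if (sum(w * dirv) < 0) w <- -w
      dirv <- w
      # the helix axis passes through the screw transform's fixed point in
      # the transverse plane: c = R^T c + t there
      Rc <- t(scr$R)  # column-vector rotation of the per-subunit step
      u <- pick_perp(dirv); u <- u / sqrt(sum(u^2))
      v <- c(dirv[2] * u[3] - dirv[3] * u[2], dirv[3] * u[1] - dirv[1] * u[3],
             dirv[1] * u[2] - dirv[2] * u[1])
      M <- rbind(c(sum(u * (Rc %*% u)), sum(u * (Rc %*% v))),
                 c(sum(v * (Rc %*% u)), sum(v * (Rc %*% v))))
      t2 <- c(sum(u * scr$t), sum(v * scr$t))
      IM <- diag(2) - M
      if (abs(det(IM)) > 1e-8) {
        c2 <- solve(IM, t2)
        axpt <- c2[1] * u + c2[2] * v
        ctr <- axpt + sum((ctr - axpt) * dirv) * dirv
      }
    }
    s_pts <- as.vector(sweep(pos, 2, ctr) %*% dirv)
    if (s_pts[1] > s_pts[length(s_pts)]) { dirv <- -dirv; s_pts <- -s_pts }
    s0 <- min(s_pts)
    at <- function(s) {
      s <- as.numeric(s)
      sweep(outer(s + s0, dirv), 2, ctr, "+")
    }
    r_pts <- sqrt(rowSums((sweep(pos, 2, ctr) -
                             outer(s_pts, as.vector(dirv)))^2))
    s_foot <- s_pts - s0
    radius <- if (length(unique(round(s_foot, 9))) >= 4)
      stats::approxfun(s_foot, r_pts, rule = 2) else function(s) rep(mean(r_pts), length(s))
    return(structure(list(
      at = at, tangent = function(s) matrix(dirv, length(s), 3, byrow = TRUE),
      radius = radius,
      s_range = c(0, max(s_pts) - s0),
      foot = function(p) as.vector(sweep(as.matrix(p), 2, ctr) %*% dirv) - s0,
      axis_points = at(s_foot), frame = "line"), class = "axis_spline"))
  }

  w <- min(as.integer(smooth_window), nrow(m))
  if (w %% 2 == 0) w <- w - 1
  if (w >= 3) {
    sm <- apply(m, 2, function(col) stats::filter(col, rep(1 / w, w), sides = 2))
    keep <- which(!is.na(sm[, 1]))
    sm <- sm[keep, , drop = FALSE]
  } else sm <- m
  if (nrow(sm) < 4) sm <- m

  tch <- c(0, cumsum(sqrt(rowSums(diff(sm)^2))))
  fx <- stats::splinefun(tch, sm[, 1], method = "natural")
  fy <- stats::splinefun(tch, sm[, 2], method = "natural")
  fz <- stats::splinefun(tch, sm[, 3], method = "natural")
  tg <- seq(0, max(tch), length.out = n_dense)
  dxyz <- cbind(fx(tg), fy(tg), fz(tg))
  s_dense <- c(0, cumsum(sqrt(rowSums(diff(dxyz)^2))))
  S <- max(s_dense)
  ax <- stats::splinefun(s_dense, dxyz[, 1], method = "natural")
  ay <- stats::splinefun(s_dense, dxyz[, 2], method = "natural")
  az <- stats::splinefun(s_dense, dxyz[, 3], method = "natural")

  at_raw <- function(s) cbind(ax(s), ay(s), az(s))
  tangent_raw <- function(s) {
    d <- cbind(ax(s, deriv = 1), ay(s, deriv = 1), az(s, deriv = 1))
    d / sqrt(rowSums(d^2))
  }
  t0 <- tangent_raw(0); t1 <- tangent_raw(S)
  p0 <- at_raw(0); p1 <- at_raw(S)
  at <- function(s) {
    s <- as.numeric(s)
    out <- matrix(NA_real_, length(s), 3)
    lo <- s < 0; hi <- s > S; mid <- !lo & !hi
    if (any(mid)) out[mid, ] <- at_raw(s[mid])
    if (any(lo)) out[lo, ] <- rep(p0, each = sum(lo)) + outer(s[lo], as.vector(t0))
    if (any(hi)) out[hi, ] <- rep(p1, each = sum(hi)) + outer(s[hi] - S, as.vector(t1))
    out
  }
  tangent <- function(s) {
    s <- as.numeric(s)
    out <- matrix(NA_real_, length(s), 3)
    lo <- s < 0; hi <- s > S; mid <- !lo & !hi
    if (any(mid)) out[mid, ] <- tangent_raw(s[mid])
    if (any(lo)) out[lo, ] <- matrix(t0, sum(lo), 3, byrow = TRUE)
    if (any(hi)) out[hi, ] <- matrix(t1, sum(hi), 3, byrow = TRUE)
    out
  }
  foot <- function(p) {
    p <- as.matrix(p)
    vapply(seq_len(nrow(p)), function(q) {
      d2 <- rowSums(sweep(dxyz, 2, p[q, ])^2)
      k <- which.min(d2)
      if (k == 1) {
        cand <- sum((p[q, ] - p0) * t0)
        if (cand < 0) return(cand)
      }
      if (k == length(s_dense)) {
        cand <- sum((p[q, ] - p1) * t1)
        if (cand > 0) return(S + cand)
      }
      lo <- s_dense[max(1, k - 2)]; hi <- s_dense[min(length(s_dense), k + 2)]
      stats::optimize(function(s) sum((at_raw(s) - p[q, ])^2),
                      lower = lo, upper = hi)$minimum
    }, numeric(1))
  }

  s_pts <- foot(pos)
  r_pts <- sqrt(rowSums((pos - at(s_pts))^2))
  radius <- if (length(unique(round(s_pts, 9))) >= 10) {
    rs <- stats::smooth.spline(s_pts, r_pts)
    function(s) stats::predict(rs, pmin(pmax(s, min(s_pts)), max(s_pts)))$y
  } else {
    stats::approxfun(s_pts, r_pts, rule = 2)
  }

  structure(list(at = at, tangent = tangent, radius = radius,
                 s_range = c(0, S), foot = foot, axis_points = dxyz,
                 frame = "spline"),
            class = "axis_spline")
}

#' @export
print.axis_spline <- function(x, ...) {
  cat(sprintf("Axis spline: arc length %.2f nm (%s)\n",
              diff(x$s_range), x$frame))
  invisible(x)
}

#' Per-interface helical rise along the central axis
#'
#' The rise at interface i is the path length along the central axis
#' between the orthogonal foot points of protomers i and i+1
#' (genetic-helix neighbours).
#'
#' @param centroids [filament_conf()] or matrix (nm).
#' @param axis an [fit_axis_spline()] result fit to the same centroids
#'   (refit if omitted).
#' @return numeric vector of n - 1 rises in Angstrom.
#' @export
instantaneous_rise <- function(centroids, axis = NULL) {
  pos <- conf_coords(as_conf_matrix(centroids))
  if (is.null(axis)) axis <- fit_axis_spline(pos)
  s <- axis$foot(pos)
  diff(s) * 10
}

# rotate the pair (N, B) by the minimal rotation taking tangent a to b
transport_frame <- function(N, B, a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  svn <- sqrt(sum(v^2))
  cth <- sum(a * b)
  if (svn < 1e-12) return(list(N = N, B = B))
  k <- v / svn
  th <- atan2(svn, cth)
  rot <- function(u) {
    u * cos(th) + c(k[2] * u[3] - k[3] * u[2], k[3] * u[1] - k[1] * u[3],
                    k[1] * u[2] - k[2] * u[1]) * sin(th) +
      k * sum(k * u) * (1 - cos(th))
  }
  list(N = rot(N), B = rot(B))
}

#' Per-interface helical twist about the central axis
#'
#' Measures twist along the short-pitch (genetic) helix between
#' consecutive protomers: each protomer's radial offset from its axial
#' foot point is expressed in a normal-binormal frame transported along
#' the axis, and the twist at interface i is the signed rotation of that
#' azimuth from protomer i to protomer i+1 about the local tangent. The
#' initial frame is the Frenet normal/binormal where the axis curvature is
#' defined; on straight stretches the parallel-transported frame is used
#' (recorded in the `frame` attribute).
#'
#' @inheritParams instantaneous_rise
#' @return numeric vector of n - 1 twists in degrees, in (-180, 180],
#'   with attribute `frame`.
#' @export
instantaneous_twist <- function(centroids, axis = NULL) {
  pos <- conf_coords(as_conf_matrix(centroids))
  n <- nrow(pos)
  if (is.null(axis)) axis <- fit_axis_spline(pos)
  s <- axis$foot(pos)
  feet <- axis$at(s)
  tang <- axis$tangent(s)

  # initial normal: Frenet where curvature is measurable, else arbitrary
  h <- max(diff(axis$s_range) * 1e-3, 1e-3)
  smid <- mean(axis$s_range)
  d2 <- (axis$tangent(smid + h) - axis$tangent(smid - h)) / (2 * h)
  frame_kind <- if (sqrt(sum(d2^2)) > 1e-4) "frenet" else "parallel"
  t1 <- tang[1, ]
  if (frame_kind == "frenet") {
    tloc <- (axis$tangent(s[1] + h) - axis$tangent(s[1] - h)) / (2 * h)
    N <- tloc - sum(tloc * t1) * t1
    if (sqrt(sum(N^2)) < 1e-8) {
      N <- pick_perp(t1); frame_kind <- "parallel"
    }
  } else N <- pick_perp(t1)
  N <- N / sqrt(sum(N^2))
  B <- c(t1[2] * N[3] - t1[3] * N[2], t1[3] * N[1] - t1[1] * N[3],
         t1[1] * N[2] - t1[2] * N[1])

  az <- numeric(n)
  for (i in seq_len(n)) {
    if (i > 1) {
      fr <- transport_frame(N, B, tang[i - 1, ], tang[i, ])
      N <- fr$N; B <- fr$B
    }
    r <- pos[i, ] - feet[i, ]
    r <- r - sum(r * tang[i, ]) * tang[i, ]
    az[i] <- atan2(sum(r * B), sum(r * N))
  }
  tw <- diff(az) * 180 / pi
  tw <- ((tw + 180) %% 360) - 180
  tw[tw == -180] <- 180
  attr(tw, "frame") <- frame_kind
  tw
}

pick_perp <- function(t1) {
  cand <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  cand - sum(cand * t1) * t1
}

#' Stitch repeated copies of a filament model end to end
#'
#' Estimates the average per-subunit screw transform of the model (by
#' rigid superposition of the chain onto itself shifted by one subunit)
#' and appends transformed copies before and after, minimising edge
#' artifacts in helical-parameter measurement. Only the central copy's
#' values should be reported.
#'
#' @param config a [filament_conf()].
#' @param copies odd number of copies (default 3).
#' @return a [filament_conf()] with `copies * n` subunits; attribute
#'   `central` holds the 1-based row range of the central copy.
#' @export
stitch_configuration <- function(config, copies = 3L) {
  copies <- as.integer(copies)
  if (copies < 1 || copies %% 2 == 0) stop("copies must be odd and >= 1")
  pos <- conf_coords(as_conf_matrix(config))
  n <- nrow(pos)
  if (copies == 1) return(as_conf_matrix(config))
  fit <- kabsch(pos[-n, , drop = FALSE], pos[-1, , drop = FALSE])
  fwd <- function(p) sweep(p %*% fit$R, 2, fit$t, "+")
  inv <- function(p) sweep(p, 2, fit$t) %*% t(fit$R)
  half <- (copies - 1L) / 2L
  pieces <- vector("list", copies)
  pieces[[half + 1L]] <- pos
  cur <- pos
  for (q in seq_len(half)) {
    for (step in seq_len(n)) cur <- fwd(cur)
    pieces[[half + 1L + q]] <- cur
  }
  cur <- pos
  for (q in seq_len(half)) {
    for (step in seq_len(n)) cur <- inv(cur)
    pieces[[half + 1L - q]] <- cur
  }
  out <- filament_conf(do.call(rbind, pieces))
  attr(out, "central") <- c(half * n + 1L, (half + 1L) * n)
  out
}

#' Measure the helical profile of a protomer-centroid chain
#'
#' High-level wrapper: optionally stitches repeated copies to suppress
#' edge artifacts, fits the variable-radius axis spline, and returns
#' per-interface rise and twist with long-pitch strand labels assigned by
#' genetic-helix index parity.
#'
#' @param centroids [filament_conf()] or n x 3 matrix (nm).
#' @param stitch number of stitched copies (1 = no stitching; 3 reports
#'   only the central copy).
#' @param smooth_window passed to [fit_axis_spline()].
#' @return a data frame: `interface` (0-based leading subunit index),
#'   `rise_A`, `twist_deg`, `strand` (1 or 2).
#' @export
measure_helical_profile <- function(centroids, stitch = 1L, smooth_window = 5L) {
  conf <- as_conf_matrix(centroids)
  n <- nrow(conf)
  work <- if (stitch > 1) stitch_configuration(conf, stitch) else conf
  axis <- fit_axis_spline(work, smooth_window = smooth_window)
  rise <- instantaneous_rise(work, axis)
  twist <- instantaneous_twist(work, axis)
  if (stitch > 1) {
    ctr <- attr(work, "central")
    idx <- ctr[1]:(ctr[2] - 1L)
    rise <- rise[idx]; twist <- twist[idx]
    lead <- seq_len(n - 1) - 1L
  } else {
    lead <- seq_len(n - 1) - 1L
  }
  data.frame(interface = lead, rise_A = as.numeric(rise),
             twist_deg = as.numeric(twist),
             strand = (lead %% 2L) + 1L)
}
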
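#' 2D filament segmentation map
#'
#' A probability map (values in [0, 1]) over a pixel grid, with physical
#' pixel size. Row-major, 0-based pixel-centre coordinates are used in
#' outputs: x = column index, y = row index.
#'
#' @param values numeric matrix of probabilities in [0, 1].
#' @param pixel_size Angstrom per pixel (default 4.32, binned micrographs).
#' @return a `segmentation_map`.
#' @export
segmentation_map <- function(values, pixel_size = 4.32) {
  values <- as.matrix(values)
  if (any(values < 0 | values > 1, na.rm = TRUE))
    stop("map values must lie in [0, 1]")
  if (pixel_size <= 0) stop("pixel size must be > 0")
  structure(list(values = values, pixel_size = pixel_size),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("Segmentation map: %d x %d px at %.2f A/px, foreground %.1f%%\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              100 * mean(x$values >= 0.3)))
  invisible(x)
}

#' Read a segmentation map from a TIFF file
#' @param file TIFF path (single-channel probability image).
#' @param pixel_size Angstrom per pixel.
#' @return a [segmentation_map()].
#' @export
read_segmentation_map <- function(file, pixel_size = 4.32) {
  img <- tiff::readTIFF(file)
  if (length(dim(img)) == 3) img <- img[, , 1]
  segmentation_map(img, pixel_size)
}

# 8-connected neighbour count for each on-pixel
neighbor_counts <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- bw
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  acc
}

# crossing number: 0->1 transitions around the 8-neighbourhood circle.
# True branch points have >= 3 transitions; staircase pixels of a simple
# 8-connected line have 2 and must not be treated as junctions.
crossing_numbers <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- bw
  sh <- function(dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  ring <- list(sh(-1, 0), sh(-1, 1), sh(0, 1), sh(1, 1),
               sh(1, 0), sh(1, -1), sh(0, -1), sh(-1, -1))
  acc <- matrix(0L, nr, nc)
  for (q in 1:8) {
    nxt <- ring[[if (q == 8) 1 else q + 1]]
    acc <- acc + (ring[[q]] == 0L & nxt == 1L)
  }
  acc
}

neighbors8 <- function(r, c, nr, nc) {
  rr <- r + c(-1, -1, -1, 0, 0, 1, 1, 1)
  cc <- c + c(-1, 0, 1, -1, 1, -1, 0, 1)
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  cbind(rr[ok], cc[ok])
}

# prune skeleton branches shorter than min_branch (walk from endpoints)
prune_branches <- function(sk, min_branch) {
  nr <- nrow(sk); nc <- ncol(sk)
  counts <- neighbor_counts(sk)
  cross <- crossing_numbers(sk)
  ep <- which(sk == 1L & counts == 1L, arr.ind = TRUE)
  kill <- matrix(0L, nr, nc)
  for (q in seq_len(nrow(ep))) {
    path <- list(ep[q, ])
    prev <- c(NA, NA)
    cur <- ep[q, ]
    repeat {
      nb <- neighbors8(cur[1], cur[2], nr, nc)
      nb <- nb[sk[nb] == 1L, , drop = FALSE]
      if (!all(is.na(prev)))
        nb <- nb[!(nb[, 1] == prev[1] & nb[, 2] == prev[2]), , drop = FALSE]
      if (nrow(nb) == 0) { hit_junction <- FALSE; break }
      if (nrow(nb) > 1 || cross[nb[1, 1], nb[1, 2]] >= 3) {
        hit_junction <- TRUE; break
      }
      prev <- cur
      cur <- nb[1, ]
      path[[length(path) + 1L]] <- cur
      if (length(path) >= min_branch) { hit_junction <- FALSE; break }
    }
    if (hit_junction && length(path) < min_branch)
      for (p in path) kill[p[1], p[2]] <- 1L
  }
  sk[kill == 1L] <- 0L
  sk
}

# label 8-connected components of a binary matrix; returns a list of
# pixel-index matrices (r, c)
components8 <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  comps <- list()
  on <- which(bw == 1L, arr.ind = TRUE)
  for (q in seq_len(nrow(on))) {
    r0 <- on[q, 1]; c0 <- on[q, 2]
    if (lab[r0, c0]) next
    id <- length(comps) + 1L
    queue <- matrix(c(r0, c0), 1, 2)
    lab[r0, c0] <- id
    members <- queue
    while (nrow(queue)) {
      cur <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      nb <- neighbors8(cur[1], cur[2], nr, nc)
      nb <- nb[bw[nb] == 1L & lab[nb] == 0L, , drop = FALSE]
      if (nrow(nb)) {
        lab[nb] <- id
        queue <- rbind(queue, nb)
        members <- rbind(members, nb)
      }
    }
    comps[[id]] <- members
  }
  comps
}

# order a component's pixels into a path by walking from an endpoint
order_path <- function(members, nr, nc) {
  sub <- matrix(0L, nr, nc)
  sub[members] <- 1L
  counts <- neighbor_counts(sub)
  ep <- which(sub == 1L & counts == 1L, arr.ind = TRUE)
  start <- if (nrow(ep)) ep[1, ] else members[1, ]
  path <- matrix(NA_integer_, nrow(members), 2)
  visited <- matrix(FALSE, nr, nc)
  cur <- start; visited[cur[1], cur[2]] <- TRUE
  path[1, ] <- cur
  k <- 1L
  repeat {
    nb <- neighbors8(cur[1], cur[2], nr, nc)
    nb <- nb[sub[nb] == 1L & !visited[nb], , drop = FALSE]
    if (!nrow(nb)) break
    # prefer 4-connected continuation for a cleaner path
    if (nrow(nb) > 1) {
      d <- abs(nb[, 1] - cur[1]) + abs(nb[, 2] - cur[2])
      nb <- nb[order(d), , drop = FALSE]
    }
    cur <- nb[1, ]
    visited[cur[1], cur[2]] <- TRUE
    k <- k + 1L
    path[k, ] <- cur
  }
  path[seq_len(k), , drop = FALSE]
}

path_end_tangent <- function(path, at_start, span = 6L) {
  n <- nrow(path)
  span <- min(span, n - 1L)
  v <- if (at_start) path[1, ] - path[1 + span, ] else path[n, ] - path[n - span, ]
  v / sqrt(sum(v^2))
}

# join ordered paths whose endpoints fall within join_dist, choosing the
# pair with the smallest tangent discontinuity when several meet
join_paths <- function(paths, join_dist) {
  repeat {
    n <- length(paths)
    if (n < 2) return(paths)
    ends <- do.call(rbind, lapply(seq_len(n), function(q) {
      p <- paths[[q]]
      rbind(c(q, 1, p[1, ]), c(q, 2, p[nrow(p), ]))
    }))
    best <- NULL; best_score <- Inf
    for (a in seq_len(nrow(ends) - 1)) for (b in (a + 1):nrow(ends)) {
      if (ends[a, 1] == ends[b, 1]) next
      d <- sqrt(sum((ends[a, 3:4] - ends[b, 3:4])^2))
      if (d > join_dist) next
      ta <- path_end_tangent(paths[[ends[a, 1]]], ends[a, 2] == 1)
      tb <- path_end_tangent(paths[[ends[b, 1]]], ends[b, 2] == 1)
      # outward tangents of a continuous filament are antiparallel
      score <- sum(ta * tb) + d / (10 * join_dist)
      if (score < best_score) { best_score <- score; best <- c(a, b) }
    }
    if (is.null(best) || best_score > -0.2) return(paths)
    ia <- ends[best[1], 1]; ib <- ends[best[2], 1]
    pa <- paths[[ia]]; pb <- paths[[ib]]
    if (ends[best[1], 2] == 1) pa <- pa[nrow(pa):1, , drop = FALSE]
    if (ends[best[2], 2] == 2) pb <- pb[nrow(pb):1, , drop = FALSE]
    paths[[ia]] <- rbind(pa, pb)
    paths[[ib]] <- NULL
  }
}

#' Extract filament tracks from a segmentation map
#'
#' Pipeline: binarize at the threshold, skeletonize, dilate to link
#' nearby filament ends, re-skeletonize, prune short branches, remove
#' pixels around junctions, join track fragments with common end points,
#' and fit a smooth 2D spline through each track.
#'
#' @param map a [segmentation_map()].
#' @param threshold binarization threshold (0.3).
#' @param link_dilation dilation radius linking filament ends, px (8).
#' @param min_branch minimum branch length kept, px (8).
#' @param junction_radius clearing radius around intersections, px (16).
#' @param min_track minimum track length kept, px.
#' @param track_smoothing smoothing factor (px^2) of the per-track spline;
#'   `NULL` budgets half a squared pixel of residual per path point
#'   (the scale of pixel-centre quantisation jitter).
#' @return list of `filament_track` objects: `id`, `path` (pixels, 1-based
#'   row/col), `curve` (arc-resampled at 1 px; columns row, col),
#'   `pixel_size`.
#' @export
extract_tracks <- function(map, threshold = 0.3, link_dilation = 8,
                           min_branch = 8, junction_radius = 16,
                           min_track = 30, track_smoothing = NULL) {
  stopifnot(inherits(map, "segmentation_map"))
  bw <- matrix(as.integer(map$values >= threshold), nrow(map$values))
  if (!any(bw == 1L)) return(list())
  sk <- thin_zhang_suen_cpp(bw)
  sk <- thin_zhang_suen_cpp(dilate_disc_cpp(sk, link_dilation))
  sk <- prune_branches(sk, min_branch)
  junctions <- matrix(as.integer(sk == 1L & crossing_numbers(sk) >= 3L), nrow(sk))
  if (any(junctions == 1L)) sk <- clear_discs_cpp(sk, junctions, junction_radius)
  comps <- components8(sk)
  comps <- comps[vapply(comps, nrow, integer(1)) >= 3]
  paths <- lapply(comps, order_path, nr = nrow(sk), nc = ncol(sk))
  paths <- join_paths(paths, join_dist = 2 * junction_radius + 6)
  paths <- paths[vapply(paths, nrow, integer(1)) >= min_track]

  lapply(seq_along(paths), function(q) {
    p <- paths[[q]]
    t <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    s_fac <- if (is.null(track_smoothing)) 0.5 * nrow(p) else track_smoothing
    fr <- spline_with_rss(t, p[, 1], s_fac)
    fc <- spline_with_rss(t, p[, 2], s_fac)
    fine <- seq(0, max(t), length.out = max(1000L, 4L * nrow(p)))
    curve <- resample_polyline(cbind(fr(fine), fc(fine)), 1)
    structure(list(id = q, path = p, curve = curve,
                   pixel_size = map$pixel_size),
              class = "filament_track")
  })
}

#' @export
print.filament_track <- function(x, ...) {
  cat(sprintf("Filament track %d: %d path px, %.0f A long\n",
              x$id, nrow(x$path), (nrow(x$curve) - 1) * x$pixel_size))
  invisible(x)
}

#' Signed curvature profile of a filament track
#'
#' Instantaneous signed curvature (positive = left turn along traversal)
#' sampled at fixed arc intervals along the track's spline, with the
#' terminal stretch omitted to avoid spline edge effects.
#'
#' @param track a `filament_track`.
#' @param sample_step sampling interval, px (3).
#' @param terminal_omit omitted length at each end, px (50).
#' @return data frame with `s_px`, `s_A` (arc position) and `kappa_um`
#'   (signed curvature, 1/um); `NULL` with a message if the track is too
#'   short.
#' @export
curvature_profile <- function(track, sample_step = 3, terminal_omit = 50) {
  stopifnot(inherits(track, "filament_track"))
  cv <- track$curve
  n <- nrow(cv)
  if ((n - 1) <= 2 * terminal_omit) {
    message("track ", track$id, " shorter than twice the terminal omission; skipped")
    return(NULL)
  }
  h <- 1 # px spacing of the resampled curve
  idx <- 2:(n - 1)
  d1 <- (cv[idx + 1, ] - cv[idx - 1, ]) / (2 * h)
  d2 <- (cv[idx + 1, ] - 2 * cv[idx, ] + cv[idx - 1, ]) / h^2
  kpx <- (d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]) /
    (rowSums(d1^2))^1.5
  s_px <- idx - 1
  keep <- s_px >= terminal_omit & s_px <= (n - 1 - terminal_omit)
  sel <- which(keep)[seq(1, sum(keep), by = sample_step)]
  data.frame(s_px = s_px[sel],
             s_A = s_px[sel] * track$pixel_size,
             kappa_um = kpx[sel] / track$pixel_size * 1e4)
}

#' Dual-sign superhelix criterion for a curvature profile
#'
#' A filament is superhelical if it contains one run of at least
#' `min_run` Angstrom where the curvature stays at or above `+kappa_thr`
#' and another run of the same length where it stays at or below
#' `-kappa_thr`. Straight filaments and uniplanar arcs (one sign only)
#' fail the criterion.
#'
#' @param profile a [curvature_profile()] data frame (or NULL).
#' @param kappa_thr curvature threshold, 1/um (1.5).
#' @param min_run minimum run length, Angstrom (200, about 7 subunit rises).
#' @return logical flag.
#' @export
classify_superhelical <- function(profile, kappa_thr = 1.5, min_run = 200) {
  if (is.null(profile) || !nrow(profile)) return(FALSE)
  run_span <- function(cond) {
    r <- rle(cond)
    if (!any(r$values)) return(0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    spans <- profile$s_A[ends] - profile$s_A[starts]
    max(spans[r$values])
  }
  run_span(profile$kappa_um >= kappa_thr) >= min_run &&
    run_span(profile$kappa_um <= -kappa_thr) >= min_run
}

#' Sample picks along superhelical filaments with per-filament NMS
#'
#' Samples segment centres at fixed spacing along each superhelical
#' track's valid arc domain, then applies greedy per-filament non-maximum
#' suppression in along-filament order: the first pick is retained and
#' every later pick closer than `min_separation` to the last retained
#' pick is dropped, so no two retained picks from one filament are closer
#' than `min_separation`.
#'
#' @param tracks list of `filament_track`s.
#' @param spacing pick spacing along the filament, Angstrom (100).
#' @param min_separation NMS separation, Angstrom (830, i.e. 768 px at
#'   bin 1).
#' @param kappa_thr,min_run,sample_step,terminal_omit classification and
#'   profiling parameters.
#' @param keep_all also emit picks from non-superhelical filaments
#'   (flagged FALSE) instead of dropping them.
#' @return a `pick_table` data frame: `x_px`, `y_px` (0-based pixel
#'   centres), `x_A`, `y_A`, `filament`, `segment`, `superhelical`.
#' @export
pick_and_suppress <- function(tracks, spacing = 100, min_separation = 830,
                              kappa_thr = 1.5, min_run = 200,
                              sample_step = 3, terminal_omit = 50,
                              keep_all = FALSE) {
  rows <- list()
  for (tr in tracks) {
    prof <- curvature_profile(tr, sample_step, terminal_omit)
    flag <- classify_superhelical(prof, kappa_thr, min_run)
    if (!flag && !keep_all) next
    if (is.null(prof)) next
    apix <- tr$pixel_size
    s_lo <- min(prof$s_A); s_hi <- max(prof$s_A)
    s_picks <- seq(s_lo, s_hi, by = spacing)
    s_keep <- nms_greedy(s_picks, min_separation)
    px <- tr$curve[round(s_keep / apix) + 1, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      x_px = px[, 2] - 1, y_px = px[, 1] - 1,
      x_A = (px[, 2] - 1) * apix, y_A = (px[, 1] - 1) * apix,
      filament = tr$id, segment = seq_along(s_keep),
      superhelical = flag)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x_px = numeric(0), y_px = numeric(0), x_A = numeric(0),
               y_A = numeric(0), filament = integer(0), segment = integer(0),
               superhelical = logical(0))
  class(out) <- c("pick_table", "data.frame")
  out
}

#' Greedy along-filament non-maximum suppression
#'
#' @param positions sorted pick positions along one filament (Angstrom).
#' @param min_separation minimum pairwise separation (Angstrom).
#' @return retained positions.
#' @export
nms_greedy <- function(positions, min_separation) {
  if (!length(positions)) return(positions)
  keep <- positions[1]
  last <- positions[1]
  for (p in positions[-1]) {
    if (p - last >= min_separation) {
      keep <- c(keep, p)
      last <- p
    }
  }
  keep
}

#' Write a pick table as a RELION-style STAR file
#'
#' Minimal STAR output with a single coordinate loop carrying
#' rlnCoordinateX/Y (pixels), the filament (helical tube) ID and the
#' superhelix flag.
#'
#' @param picks a `pick_table` from [pick_and_suppress()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_star <- function(picks, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("", "data_", "", "loop_",
               "_rlnCoordinateX #1", "_rlnCoordinateY #2",
               "_rlnHelicalTubeID #3", "_rlnClassNumber #4"), con)
  if (nrow(picks))
    writeLines(sprintf("%12.4f %12.4f %6d %6d",
                       picks$x_px, picks$y_px, picks$filament,
                       as.integer(picks$superhelical)), con)
  invisible(file)
}
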
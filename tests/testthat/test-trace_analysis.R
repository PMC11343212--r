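test_that("trace fitting resamples evenly and handles degenerate input", {
  s <- seq(0, 500, by = 5)
  line <- cbind(s, 0 * s, 0 * s)
  tr <- fit_trace(line, units = "nm")
  expect_equal(nrow(tr$points), floor(500 / 0.96) + 1)
  step <- sqrt(rowSums(diff(tr$points)^2))
  expect_true(all(abs(step - 0.96) / 0.96 < 0.01))
  ct <- curvature_torsion(tr)
  expect_true(all(abs(ct$kappa_um) < 1e-4, na.rm = TRUE))
  expect_error(fit_trace(line[1:5, ], units = "nm"), "at least 10")
  dup <- line[rep(1:101, each = 2), ]
  expect_equal(nrow(fit_trace(dup, units = "nm")$points), nrow(tr$points))
})

test_that("noisy superhelix traces stay within 1 nm RMS of the true path", {
  g <- gen_superhelix_trace(160, 10, 10, 800, noise_sd_nm = 1, seed = 13)
  tr <- fit_trace(g$markers, units = "nm")
  t <- seq(0, 800, length.out = 8000)
  truth <- cbind(10 * sin(2 * pi * t / 160), 10 * cos(2 * pi * t / 160), t)
  d <- vapply(seq_len(nrow(tr$points)), function(q)
    sqrt(min(colSums((t(truth) - tr$points[q, ])^2))), numeric(1))
  expect_lt(sqrt(mean(d^2)), 1)
})

test_that("curvature and torsion match closed forms for circle and helix", {
  th <- seq(0, 2 * pi, by = 0.96 / 500)  # exact 0.96 nm arc steps
  circ <- cbind(500 * cos(th), 500 * sin(th), 0 * th)
  ct <- curvature_torsion(circ)
  mid <- 10:(nrow(ct) - 10)
  expect_true(all(abs(ct$kappa_um[mid] - 2) / 2 < 0.01))
  expect_true(all(abs(ct$tau_um[mid]) < 0.01))
  a <- 100; b <- 50
  t <- seq(0, 6 * pi, by = 0.96 / sqrt(a^2 + b^2))  # even arc steps
  hel <- cbind(a * cos(t), a * sin(t), b * t)
  cth <- curvature_torsion(hel)
  mid <- 10:(nrow(cth) - 10)
  expect_true(all(abs(cth$kappa_um[mid] - 1000 * a / (a^2 + b^2)) /
                    (1000 * a / (a^2 + b^2)) < 0.01))
  expect_true(all(abs(cth$tau_um[mid] - 1000 * b / (a^2 + b^2)) /
                    (1000 * b / (a^2 + b^2)) < 0.01))
  # noisy generated arc within 10% of program
  ga <- gen_planar_arc_trace(2, 500, noise_sd_nm = 0.5, seed = 3)
  ck <- curvature_torsion(fit_trace(ga$markers, units = "nm"))
  mid <- 30:(nrow(ck) - 30)
  expect_lt(abs(median(ck$kappa_um[mid]) - 2) / 2, 0.1)
})

test_that("alignment is invariant to traversal order and rigid motion", {
  g <- gen_superhelix_trace(160, 20, 8, 900, noise_sd_nm = 1, seed = 5)
  seg <- find_oscillatory_segments(fit_trace(g$markers, units = "nm"))[[1]]
  pts <- spiractin:::reconstruct_points(seg)
  al <- pca_align(list(pts, pts[nrow(pts):1, ], rigid_transform(pts)))
  expect_equal(al[[1]]$pc2, al[[2]]$pc2, tolerance = 1e-8)
  expect_equal(al[[1]]$pc3, al[[2]]$pc3, tolerance = 1e-8)
  expect_equal(al[[1]]$pc2, al[[3]]$pc2, tolerance = 1e-8)
  # aligned segments are centred on a PC2 minimum (positive curvature there)
  ctr <- which.min(abs(al[[1]]$arc))
  expect_lt(al[[1]]$pc2[ctr], 0)
  expect_error(pca_align(list(cbind(seq(0, 400, by = 0.96), 0, 0))), "flat")
  expect_error(pca_align(list()), "at least one")
})

test_that("spiral statistics recover programmed wavelength, offset and axes", {
  g <- gen_superhelix_trace(160, 10, 10, 900, noise_sd_nm = 0, seed = 1)
  st <- spiral_stats(pca_align(find_oscillatory_segments(
    fit_trace(g$markers, units = "nm")))[[1]])
  expect_lt(abs(st$wavelength_nm - 160), 2)
  expect_lt(abs(st$phase_offset - 0.25), 0.02)
  expect_false(st$significant)  # 10 nm amplitude sits below the 15 nm cutoff
  ge <- gen_superhelix_trace(160, 20, 8, 900, noise_sd_nm = 0, seed = 2)
  ste <- spiral_stats(pca_align(find_oscillatory_segments(
    fit_trace(ge$markers, units = "nm")))[[1]])
  expect_lt(abs(ste$major_nm - 20) / 20, 0.15)
  expect_lt(abs(ste$minor_nm - 8) / 8, 0.15)
  expect_gt(ste$major_nm, ste$minor_nm)
  expect_true(ste$phase_offset > 0.2 && ste$phase_offset < 0.3)
})

test_that("planar sinusoids are flagged with undefined offset", {
  g <- gen_superhelix_trace(160, 20, 0, 900, noise_sd_nm = 0.2, seed = 4)
  st <- spiral_stats(pca_align(find_oscillatory_segments(
    fit_trace(g$markers, units = "nm")))[[1]])
  expect_false(st$offset_defined)
  expect_lt(st$amplitude_pc3, 2)
  # small-amplitude spiral flagged insignificant
  gs <- gen_superhelix_trace(160, 8, 6, 900, noise_sd_nm = 0.2, seed = 6)
  sts <- spiral_stats(pca_align(find_oscillatory_segments(
    fit_trace(gs$markers, units = "nm")))[[1]])
  expect_false(sts$significant)
})

test_that("wavelength recovery is unbiased across 100-250 nm", {
  errs <- vapply(seq(100, 250, by = 25), function(wl) {
    g <- gen_superhelix_trace(wl, 15, 10, 1000, noise_sd_nm = 2, seed = wl)
    segs <- find_oscillatory_segments(fit_trace(g$markers, units = "nm"))
    st <- spiral_stats(segs[[1]])
    abs(st$wavelength_nm - wl)
  }, numeric(1))
  expect_lt(median(errs), 5)
})

test_that("straight and single-arc traces yield no oscillatory segments", {
  gs <- gen_straight_trace(600, noise_sd_nm = 0.3, seed = 2)
  expect_length(find_oscillatory_segments(fit_trace(gs$markers, units = "nm")), 0)
  ga <- gen_planar_arc_trace(0.8, 600, noise_sd_nm = 0.3, seed = 2)
  expect_length(find_oscillatory_segments(fit_trace(ga$markers, units = "nm")), 0)
})

test_that("ice-plane angles are measured as programmed", {
  g <- gen_superhelix_trace(160, 20, 8, 900, noise_sd_nm = 0.5, seed = 2)
  seg <- pca_align(find_oscillatory_segments(fit_trace(g$markers, units = "nm")))[[1]]
  for (ang in c(0, 30, 60, 90)) {
    pp <- gen_plane_points(ang, seed = 7)
    expect_lt(abs(plane_angle(seg, pp) - ang), 2)
  }
  expect_error(plane_angle(seg, cbind(1:5, 2 * (1:5), 3 * (1:5))), "collinear")
})

test_that("KS test matches construction identity and brute-force oracle", {
  n <- 20
  x <- qnorm((seq_len(n) - 0.5) / n)
  res <- ks_uniformity_test(x, "standard-normal")
  expect_equal(res$D, 0.5 / n, tolerance = 1e-12)
  set.seed(8)
  y <- rnorm(8, 0.3, 1.2)
  res8 <- ks_uniformity_test(y, "standard-normal")
  expect_equal(res8$D, oracle_ks_D(y, pnorm), tolerance = 1e-12)
  expect_equal(res8$p_value,
               suppressWarnings(stats::ks.test(y, pnorm)$p.value),
               tolerance = 1e-12)
  expect_error(ks_uniformity_test(c(1, 2)), "at least 3")
})

test_that("samples drawn from the reference rarely reject it", {
  p <- vapply(1:20, function(s) {
    set.seed(s)
    ks_uniformity_test(rnorm(1000), "standard-normal")$p_value
  }, numeric(1))
  expect_gte(mean(p > 0.05), 0.9)
})
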
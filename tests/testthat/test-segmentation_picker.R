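make_benchmark <- function(seed = 1) {
  specs <- list(
    seg_straight(length_px = 600, start = c(120, 60)),
    seg_arc(curvature_um = 2, length_px = 600, start = c(320, 60)),
    seg_s(curvature_um = 2, run_px = 300, start = c(560, 60))
  )
  gen_segmentation_image(specs, nrow_px = 768, ncol_px = 768, seed = seed)
}

test_that("blank maps yield no tracks and invalid maps are rejected", {
  g <- gen_segmentation_image(list(), seed = 1)
  expect_length(extract_tracks(g$map), 0)
  expect_error(segmentation_map(matrix(2, 4, 4)), "\\[0, 1\\]")
  expect_error(segmentation_map(matrix(0.5, 4, 4), pixel_size = -1), "> 0")
})

test_that("a single straight filament produces one full-length track", {
  g <- gen_segmentation_image(list(seg_straight(length_px = 600, start = c(120, 60))),
                              seed = 2)
  tks <- extract_tracks(g$map)
  expect_length(tks, 1)
  expect_lt(abs(nrow(tks[[1]]$curve) - 600), 10)
  pr <- curvature_profile(tks[[1]])
  expect_true(all(abs(pr$kappa_um) < 0.3))
})

test_that("crossing filaments are re-joined into two tracks", {
  specs <- list(seg_straight(550, c(380, 100), 20), seg_straight(550, c(260, 120), -20))
  g <- gen_segmentation_image(specs, seed = 3)
  tks <- extract_tracks(g$map)
  expect_length(tks, 2)
  expect_true(all(vapply(tks, function(t) nrow(t$path), numeric(1)) > 350))
})

test_that("arc curvature magnitude matches the program", {
  g <- gen_segmentation_image(list(seg_arc(2, 600, c(320, 60))), seed = 4)
  tks <- extract_tracks(g$map)
  expect_length(tks, 1)
  pr <- curvature_profile(tks[[1]])
  expect_lt(abs(median(abs(pr$kappa_um)) - 2) / 2, 0.05)
  # single sign throughout: not superhelical
  expect_false(classify_superhelical(pr))
})

test_that("S-shaped filaments change curvature sign near the inflection", {
  g <- gen_segmentation_image(list(seg_s(2, run_px = 300, start = c(560, 60))),
                              seed = 5)
  tks <- extract_tracks(g$map)
  expect_length(tks, 1)
  pr <- curvature_profile(tks[[1]])
  signs <- sign(pr$kappa_um[abs(pr$kappa_um) > 0.5])
  expect_equal(length(unique(signs)), 2L)
  flip_at <- pr$s_px[which(diff(sign(pr$kappa_um)) != 0)[1]]
  expect_lt(abs(flip_at - 300), 10 + 50)  # inflection position (terminal offset aside)
  expect_true(classify_superhelical(pr))
})

test_that("the dual-sign criterion separates the synthetic benchmark perfectly", {
  g <- make_benchmark()
  tks <- extract_tracks(g$map)
  expect_length(tks, 3)
  flags <- vapply(tks, function(t) classify_superhelical(curvature_profile(t)),
                  logical(1))
  # match tracks to ground-truth filaments by start position
  expect_equal(sum(flags), sum(g$truth$superhelical))
  expect_equal(sum(!flags), sum(!g$truth$superhelical))
  # empty profile is not superhelical
  expect_false(classify_superhelical(NULL))
})

test_that("greedy NMS matches its oracle and the worked example", {
  expect_equal(nms_greedy(seq(0, 1000, by = 100), 830), c(0, 900))
  expect_equal(nms_greedy(numeric(0), 830), numeric(0))
  expect_equal(nms_greedy(5, 830), 5)
  set.seed(31)
  for (q in 1:25) {
    n <- sample(2:12, 1)
    pos <- sort(runif(n, 0, 3000))
    sep <- runif(1, 100, 1500)
    expect_equal(nms_greedy(pos, sep), oracle_nms_exhaustive(pos, sep))
  }
})

test_that("picks come only from superhelical filaments and never cross-suppress", {
  g <- make_benchmark()
  tks <- extract_tracks(g$map)
  picks <- pick_and_suppress(tks)
  expect_true(all(picks$superhelical))
  expect_equal(length(unique(picks$filament)), 1L)
  expect_true(all(picks$x_px >= 0 & picks$x_px < 768))
  # keep_all mode emits all filaments, suppression still per filament
  pall <- pick_and_suppress(tks, keep_all = TRUE)
  expect_equal(length(unique(pall$filament)), 3L)
  for (f in unique(pall$filament)) {
    s <- sort(pall$x_A[pall$filament == f]^0)  # per-filament picks exist
    expect_gte(length(s), 1)
  }
})

test_that("the pick pipeline is deterministic and writes STAR output", {
  g <- make_benchmark()
  p1 <- pick_and_suppress(extract_tracks(g$map))
  p2 <- pick_and_suppress(extract_tracks(g$map))
  expect_identical(p1, p2)
  f <- tempfile(fileext = ".star")
  write_star(p1, f)
  lines <- readLines(f)
  expect_true(any(grepl("_rlnCoordinateX", lines)))
  expect_true(any(grepl("_rlnHelicalTubeID", lines)))
  expect_equal(sum(grepl("^\\s*[0-9]", lines)), nrow(p1))
})

test_that("segmentation maps round trip through TIFF", {
  g <- make_benchmark()
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(g$map$values, f, bits.per.sample = 32L)
  back <- read_segmentation_map(f, pixel_size = 4.32)
  expect_equal(back$values, g$map$values, tolerance = 1e-6)
})
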
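test_that("pixel_to_stage applies rotation, scale, then origin translation", {
  m <- camera_mapping(1.3, 1.3, origin = stage_point(100, 200))
  p0 <- pixel_to_stage(c(0, 0), m)
  expect_equal(c(p0$x_um, p0$y_um), c(100, 200))
  p1 <- pixel_to_stage(c(10, 20), m)
  expect_equal(c(p1$x_um, p1$y_um), c(113, 226))

  # rotation oracle: multiply the 2x2 rotation matrix by hand
  rot <- pi / 2
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  expected <- as.numeric(R %*% c(10, 0))
  mr <- camera_mapping(1, 1, rotation_rad = rot)
  pr <- pixel_to_stage(c(10, 0), mr)
  expect_equal(c(pr$x_um, pr$y_um), expected, tolerance = 1e-12)
})

test_that("stage_to_pixel inverts pixel_to_stage", {
  m <- camera_mapping(1.3, 1.3, origin = stage_point(100, 200))
  expect_equal(stage_to_pixel(c(113, 226), m), c(10, 20), tolerance = 1e-12)
  expect_equal(stage_to_pixel(pixel_to_stage(c(37, 41), m), m), c(37, 41),
               tolerance = 1e-9)
})

test_that("pixel/stage round trip is exact for 100 random mappings", {
  set.seed(42)
  worst <- 0
  for (k in 1:100) {
    m <- camera_mapping(runif(1, 0.1, 5), runif(1, 0.1, 5),
                        origin = stage_point(runif(1, -1e4, 1e4),
                                             runif(1, -1e4, 1e4)),
                        rotation_rad = runif(1, -pi, pi))
    p <- matrix(runif(20, -2000, 2000), ncol = 2)
    back <- stage_to_pixel(pixel_to_stage(p, m), m)
    worst <- max(worst, max(abs(back - p)))
  }
  expect_lt(worst, 1e-9)
})

test_that("non-finite coordinates are rejected", {
  m <- camera_mapping(1, 1)
  expect_error(pixel_to_stage(c(NA, 0), m), class = "sf_coordinate_error")
  expect_error(stage_to_pixel(c(Inf, 0), m), class = "sf_coordinate_error")
  expect_error(camera_mapping(0, 1), class = "sf_coordinate_error")
})

test_that("plan_tiles matches the per-axis count formula", {
  pl <- plan_tiles(region(0, 0, 2000, 1000), objective("t", 1, 500, 400), 0.10)
  expect_equal(pl$nx, 5)   # ceil((2000-500)/450)+1
  expect_equal(pl$ny, 3)   # ceil((1000-400)/360)+1
  expect_equal(nrow(pl$centers), 15)

  # degenerate: fov larger than region -> one centered tile
  pl1 <- plan_tiles(region(0, 0, 300, 300), objective("t", 1, 500, 400), 0.3)
  expect_equal(nrow(pl1$centers), 1)
  expect_equal(pl1$centers$x_um, 150)
  expect_equal(pl1$centers$y_um, 150)

  # region equal to one fov, overlap 0 -> exactly one tile
  pl2 <- plan_tiles(region(10, 20, 500, 400), objective("t", 1, 500, 400), 0)
  expect_equal(nrow(pl2$centers), 1)
})

test_that("plan_tiles covers the region (brute-force raster oracle)", {
  set.seed(7)
  for (k in 1:8) {
    w <- runif(1, 300, 4000); h <- runif(1, 300, 3000)
    fw <- runif(1, 200, 900); fh <- runif(1, 200, 900)
    ov <- runif(1, 0, 0.5)
    pl <- plan_tiles(region(0, 0, w, h), objective("t", 1, fw, fh), ov)
    xs <- seq(0.5, w - 0.5, by = 1); ys <- seq(0.5, h - 0.5, by = 1)
    covx <- rep(FALSE, length(xs)); covy <- rep(FALSE, length(ys))
    for (i in seq_len(nrow(pl$centers))) {
      covx <- covx | (xs >= pl$centers$x_um[i] - fw / 2 - 1e-9 &
                      xs <= pl$centers$x_um[i] + fw / 2 + 1e-9)
      covy <- covy | (ys >= pl$centers$y_um[i] - fh / 2 - 1e-9 &
                      ys <= pl$centers$y_um[i] + fh / 2 + 1e-9)
    }
    expect_true(all(covx) && all(covy))
  }
})

test_that("plan_tiles tile count is monotone in overlap and fov", {
  reg <- region(0, 0, 3000, 2000)
  counts_ov <- vapply(c(0, 0.1, 0.3, 0.5, 0.7),
                      function(ov) nrow(plan_tiles(reg, objective("t", 1, 500, 400), ov)$centers),
                      1)
  expect_true(all(diff(counts_ov) >= 0))
  counts_fov <- vapply(c(300, 400, 600, 900),
                       function(f) nrow(plan_tiles(reg, objective("t", 1, f, f), 0.1)$centers),
                       1)
  expect_true(all(diff(counts_fov) <= 0))
})

test_that("plan_tiles orders centers in snake order", {
  pl <- plan_tiles(region(0, 0, 2000, 1000), objective("t", 1, 500, 400), 0.10)
  for (r in unique(pl$centers$row)) {
    xs <- pl$centers$x_um[pl$centers$row == r]
    if (r %% 2 == 1) expect_true(all(diff(xs) > 0)) else expect_true(all(diff(xs) < 0))
  }
})

test_that("apply_offset handles identity, translation, rotation and inverse", {
  s <- stage_point(10, 10)
  id <- apply_offset(s, offset_correction())
  expect_equal(c(id$x_um, id$y_um), c(10, 10))
  tr <- apply_offset(s, offset_correction(5, -3))
  expect_equal(c(tr$x_um, tr$y_um), c(15, 7))
  half <- apply_offset(stage_point(10, 0), offset_correction(0, 0, pi))
  expect_equal(c(half$x_um, half$y_um), c(-10, 0), tolerance = 1e-9)

  corr <- offset_correction(12, -7, 0.3)
  piv <- stage_point(5, 8)
  back <- apply_offset(apply_offset(s, corr, piv), corr, piv, inverse = TRUE)
  expect_equal(c(back$x_um, back$y_um), c(10, 10), tolerance = 1e-9)
})

test_that("translations compose commutatively under apply_offset", {
  s <- matrix(runif(10, -100, 100), ncol = 2)
  a <- offset_correction(3, -4); b <- offset_correction(-11, 6)
  ab <- apply_offset(apply_offset(s, a), b)
  ba <- apply_offset(apply_offset(s, b), a)
  expect_equal(ab, ba, tolerance = 1e-12)
})

test_that("positions lists round-trip through JSON", {
  pl <- plan_tiles(region(0, 0, 2000, 1000), objective("t", 1, 500, 400), 0.10)
  f <- withr::local_tempfile(fileext = ".json")
  write_positions(pl, f, z_um = 12.5)
  got <- read_positions(f)
  expect_equal(nrow(got), 15)
  expect_equal(got$x_um, pl$centers$x_um)
  expect_equal(got$y_um, pl$centers$y_um)
  expect_equal(unique(got$z_um), 12.5)
})
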
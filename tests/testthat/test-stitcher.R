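test_that("phase correlation recovers exact and rolled shifts", {
  set.seed(4)
  a <- matrix(runif(96 * 128), 96, 128)
  same <- phase_correlate(a, a)
  expect_equal(c(same$dx_px, same$dy_px), c(0, 0), tolerance = 1e-6)
  expect_gt(same$confidence, 0.9)

  pc <- phase_correlate(a, roll2(a, 5, -3))
  expect_equal(c(pc$dx_px, pc$dy_px), c(5, -3), tolerance = 1e-6)

  noise <- phase_correlate(a, matrix(runif(96 * 128), 96, 128))
  expect_lt(noise$confidence, 0.1)
  expect_false(noise$reliable)
})

test_that("pairwise offsets recover known jitter on a simulated grid", {
  # 2x2 grid cut from one fully textured scene with known integer jitter
  cam <- camera_model(256, 192)
  obj20 <- objective_from_camera(cam, 20)
  umpp <- cam$ref_um_per_px_at_1x / 20
  scene <- smooth_texture(600, 800, seed = 11, sigma = 2)
  pl <- plan_tiles(region(0, 0, 230 * umpp * 2, 170 * umpp * 2), obj20, 0.10)
  expect_equal(c(pl$nx, pl$ny), c(2, 2))
  set.seed(99)
  jit <- matrix(sample(-5:5, nrow(pl$centers) * 2, replace = TRUE), ncol = 2)
  tiles <- lapply(seq_len(nrow(pl$centers)), function(k) {
    nom <- stage_point(pl$centers$x_um[k], pl$centers$y_um[k])
    # top-left pixel of the cut in scene coordinates, with jitter
    c0 <- round(nom$x_um / umpp - cam$sensor_w_px / 2) + 100 + jit[k, 1]
    r0 <- round(nom$y_um / umpp - cam$sensor_h_px / 2) + 100 + jit[k, 2]
    img <- scene[(r0 + 1):(r0 + cam$sensor_h_px), (c0 + 1):(c0 + cam$sensor_w_px)]
    tile_image(img, nom, field_mapping(nom, obj20, cam), k)
  })
  off <- pairwise_offsets(tiles, pl)
  expect_equal(nrow(off), 4)
  for (k in seq_len(nrow(off))) {
    i <- off$i[k]; j <- off$j[k]
    ndx <- (pl$centers$x_um[pl$centers$index == j] -
            pl$centers$x_um[pl$centers$index == i]) / umpp
    ndy <- (pl$centers$y_um[pl$centers$index == j] -
            pl$centers$y_um[pl$centers$index == i]) / umpp
    # content of tile j sits at its cut position: displacement includes jitter
    tdx <- round(pl$centers$x_um[pl$centers$index == j] / umpp - cam$sensor_w_px / 2) -
      round(pl$centers$x_um[pl$centers$index == i] / umpp - cam$sensor_w_px / 2) +
      jit[j, 1] - jit[i, 1]
    tdy <- round(pl$centers$y_um[pl$centers$index == j] / umpp - cam$sensor_h_px / 2) -
      round(pl$centers$y_um[pl$centers$index == i] / umpp - cam$sensor_h_px / 2) +
      jit[j, 2] - jit[i, 2]
    expect_lt(abs(off$dx_px[k] - tdx), 0.5)
    expect_lt(abs(off$dy_px[k] - tdy), 0.5)
  }
})

test_that("featureless tiles drop out and fall back to nominal placement", {
  sl <- make_slide(small_spec(n_objects = 0))
  cam <- camera_model()
  obj20 <- objective_from_camera(cam, 20)
  reg <- region(40000, 12000, 880, 330)
  pl <- plan_tiles(reg, obj20, 0.25)
  tiles <- lapply(seq_len(nrow(pl$centers)), function(k) {
    nom <- stage_point(pl$centers$x_um[k], pl$centers$y_um[k])
    tile_image(render_field(sl, nom, obj20, cam, seed = k), nom,
               field_mapping(nom, obj20, cam), k)
  })
  off <- pairwise_offsets(tiles, pl)
  expect_equal(nrow(off), 0)
  lay <- global_place(tiles, off)
  expect_equal(lay$provenance, "stage_only")
  expect_equal(lay$positions$x_px,
               vapply(tiles, function(t) t$mapping$origin$x_um, 1) / 0.5)
})

test_that("single tiles yield no pairwise offsets", {
  cam <- camera_model()
  obj20 <- objective_from_camera(cam, 20)
  pl <- plan_tiles(region(0, 0, 100, 100), obj20, 0.1)
  t1 <- tile_image(matrix(0.5, 64, 64), stage_point(50, 50),
                   field_mapping(stage_point(50, 50), obj20, cam), 1)
  expect_equal(nrow(pairwise_offsets(list(t1), pl)), 0)
})

test_that("global placement is exact for consistent offsets", {
  cam <- camera_model()
  obj20 <- objective_from_camera(cam, 20)
  mk <- function(x, y, i) tile_image(matrix(0.5, 64, 64), stage_point(x, y),
                                     field_mapping(stage_point(x, y), obj20, cam), i)
  tiles <- list(mk(0, 0, 1), mk(200, 0, 2), mk(400, 0, 3))
  off <- data.frame(i = c(1, 2), j = c(2, 3), dx_px = c(400, 400),
                    dy_px = c(1, -1), confidence = c(0.9, 0.9))
  lay <- global_place(tiles, off)
  expect_equal(lay$provenance, "refined")
  expect_equal(diff(lay$positions$x_px), c(400, 400), tolerance = 1e-6)
  expect_equal(diff(lay$positions$y_px), c(1, -1), tolerance = 1e-6)

  # no offsets -> nominal placement
  lay0 <- global_place(tiles, NULL)
  expect_equal(lay0$provenance, "stage_only")
})

test_that("inconsistent loops resolve to the least-squares optimum", {
  cam <- camera_model()
  obj20 <- objective_from_camera(cam, 20)
  mk <- function(x, y, i) tile_image(matrix(0.5, 64, 64), stage_point(x, y),
                                     field_mapping(stage_point(x, y), obj20, cam), i)
  tiles <- list(mk(0, 0, 1), mk(100, 0, 2), mk(0, 80, 3), mk(100, 80, 4))
  # cycle 1->2->4->3->1 whose measured offsets sum to (2, 0): inconsistent
  off <- data.frame(i = c(1, 2, 1, 3),
                    j = c(2, 4, 3, 4),
                    dx_px = c(201, 1, 0, 202),
                    dy_px = c(0, 160, 160, 0),
                    confidence = c(1, 0.5, 0.8, 0.25))
  lay <- global_place(tiles, off)

  # independent oracle: numeric minimisation of the weighted objective
  obj_fn <- function(p) {
    px <- c(0, p[1:3]); py <- c(0, p[4:6])    # anchor tile 1 at 0
    sum(off$confidence * ((px[off$j] - px[off$i] - off$dx_px)^2 +
                          (py[off$j] - py[off$i] - off$dy_px)^2))
  }
  opt <- optim(rep(0, 6), obj_fn, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  got <- c(lay$positions$x_px[2:4] - lay$positions$x_px[1],
           lay$positions$y_px[2:4] - lay$positions$y_px[1])
  expect_equal(got, opt$par, tolerance = 1e-5)
})

test_that("mosaics reproduce single tiles and known overlaps", {
  cam <- camera_model()
  obj20 <- objective_from_camera(cam, 20)
  img <- smooth_texture(64, 64, seed = 5)
  t1 <- tile_image(img, stage_point(16, 16),
                   field_mapping(stage_point(16, 16), obj20, cam), 1)
  lay <- global_place(list(t1), NULL)
  expect_equal(render_mosaic(list(t1), lay, "overwrite")$image, img)

  # two tiles with an exact known shift: overwrite keeps the later tile
  sh <- 32L
  t2 <- tile_image(smooth_texture(64, 64, seed = 6),
                   stage_point(16 + sh * 0.5, 16),
                   field_mapping(stage_point(16 + sh * 0.5, 16), obj20, cam), 2)
  lay2 <- global_place(list(t1, t2), NULL)
  mos <- render_mosaic(list(t1, t2), lay2, "overwrite")$image
  expect_equal(dim(mos), c(64, 64 + sh))
  expect_equal(mos[, (sh + 1):(64 + sh)], t2$image)
})

test_that("a stitched mosaic matches a direct render of the region", {
  sl <- make_slide(small_spec(n_objects = 12,
                              coverslip = region(30000, 8000, 4000, 4000),
                              seed = 8))
  cam0 <- camera_model(read_noise_sd = 0)
  obj20 <- objective_from_camera(cam0, 20)
  umpp <- cam0$ref_um_per_px_at_1x / 20
  ctr <- c(sl$objects$x_um[2], sl$objects$y_um[2])
  reg <- region(ctr[1] - 440, ctr[2] - 330, 880, 660)
  pl <- plan_tiles(reg, obj20, 0.25)
  tiles <- lapply(seq_len(nrow(pl$centers)), function(k) {
    nom <- stage_point(pl$centers$x_um[k], pl$centers$y_um[k])
    tile_image(render_field(sl, nom, obj20, cam0), nom,
               field_mapping(nom, obj20, cam0), k)
  })
  lay <- global_place(tiles, pairwise_offsets(tiles, pl))
  mos <- render_mosaic(tiles, lay, "linear")

  big_cam <- camera_model(ncol(mos$image), nrow(mos$image),
                          ref_um_per_px_at_1x = cam0$ref_um_per_px_at_1x,
                          read_noise_sd = 0)
  mctr <- stage_point((mos$origin_px[1] + ncol(mos$image) / 2) * umpp,
                      (mos$origin_px[2] + nrow(mos$image) / 2) * umpp)
  direct <- render_field(sl, mctr, obj20, big_cam)
  mae <- mean(abs(mos$image - direct)) * 255
  expect_lt(mae, 2)
})
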
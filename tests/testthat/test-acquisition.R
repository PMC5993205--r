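test_that("imaging cost arithmetic matches the two-phase economy model", {
  a <- imaging_cost(1, 0, 5, 20)
  expect_equal(a$n_exhaustive_highres, 16)
  expect_equal(a$n_highres_images, 0)

  b <- imaging_cost(250, 300, 5, 20)
  expect_equal(b$n_exhaustive_highres, 4000)
  expect_true(b$n_exhaustive_highres > 3000 && b$n_exhaustive_highres < 6500)
  expect_equal(b$n_lowres_images, 250)
  expect_equal(b$n_highres_images, 300)
  expect_equal(b$economy_ratio, 4000 / (300 + 250 / 16))
  expect_gt(b$economy_ratio, 10)

  # idempotent pure arithmetic
  expect_equal(unclass(imaging_cost(250, 300, 5, 20)), unclass(b))
})

test_that("slide pools load in cartridge order with seeded poses", {
  cfg <- small_config(n_objects = 3)
  st <- wf_store(withr::local_tempdir())
  pool <- simulate_slide_pool(st, 3, cfg)
  expect_equal(pool$slide_id, sprintf("slide%03d", 1:3))

  cfg0 <- cfg; cfg0$loader$sd_um <- 0; cfg0$loader$sd_rad <- 0
  first <- load_next(pool, st, cfg0)
  expect_equal(first$slide_id, "slide001")
  expect_equal(unclass(first$slide$pose), unclass(offset_correction()))
  second <- load_next(first$pool, st, cfg0)
  expect_equal(second$slide_id, "slide002")
  third <- load_next(second$pool, st, cfg0)
  expect_null(load_next(third$pool, st, cfg0))   # end-of-pool signal
})

test_that("image_region writes exactly the planned tiles with metadata", {
  cfg <- small_config(n_objects = 3)
  st <- wf_store(withr::local_tempdir())
  simulate_slide_pool(st, 1, cfg)
  sl <- read_slide(file.path(st$path, "slides", "slide001.json"))
  cam <- camera_model()
  obj5 <- objective_from_camera(cam, 5)
  one <- image_region(sl, region(40000, 12000, 500, 400), obj5, cam,
                      st$path, "slide001", "single", seed = 2)
  expect_equal(one$n_total, 1)
  meta <- read_dataset(st$path, "slide001", "single")$meta
  expect_equal(nrow(meta$entries), 1)
  expect_equal(meta$entries$x_um, 40250)
  expect_equal(meta$entries$y_um, 12200)

  multi <- image_region(sl, region(34000, 10000, 4000, 3000), obj5, cam,
                        st$path, "slide001", "multi", seed = 3)
  expect_equal(multi$n_total, nrow(multi$plan$centers))
  expect_equal(nrow(read_dataset(st$path, "slide001", "multi")$meta$entries),
               multi$n_total)

  expect_error(image_region(sl, region(70000, 20000, 20000, 20000), obj5, cam,
                            st$path, "slide001", "oob"),
               class = "sf_out_of_bounds")
})

test_that("interrupted tiled passes resume with each tile acquired once", {
  cfg <- small_config(n_objects = 3)
  st <- wf_store(withr::local_tempdir())
  simulate_slide_pool(st, 1, cfg)
  sl <- read_slide(file.path(st$path, "slides", "slide001.json"))
  cam <- camera_model()
  obj5 <- objective_from_camera(cam, 5)
  reg <- region(34000, 10000, 4000, 3000)
  r1 <- tryCatch(
    image_region(sl, reg, obj5, cam, st$path, "slide001", "p",
                 seed = 2, interrupt_after_tiles = 2),
    sf_interrupt = function(e) "interrupted")
  expect_equal(r1, "interrupted")
  expect_equal(nrow(read_dataset(st$path, "slide001", "p")$meta$entries), 2)
  r2 <- image_region(sl, reg, obj5, cam, st$path, "slide001", "p", seed = 2)
  expect_equal(r2$n_rendered, r2$n_total - 2)
  ent <- read_dataset(st$path, "slide001", "p")$meta$entries
  expect_equal(sort(ent$tile_index), seq_len(r2$n_total))
  expect_equal(anyDuplicated(ent$tile_index), 0)
})

test_that("live-view survey detects objects without storing frames", {
  cfg <- small_config(n_objects = 0)
  st <- wf_store(withr::local_tempdir())
  simulate_slide_pool(st, 1, cfg)
  sl <- read_slide(file.path(st$path, "slides", "slide001.json"))
  sv0 <- survey_slide(sl, config = cfg, slide_id = "slide001", seed = 1)
  expect_equal(length(sv0$rois), 0)

  cfg2 <- small_config(n_objects = 25, seed = 21)
  st2 <- wf_store(withr::local_tempdir())
  simulate_slide_pool(st2, 1, cfg2)
  sl2 <- read_slide(file.path(st2$path, "slides", "slide001.json"))
  sv <- survey_slide(sl2, config = cfg2, slide_id = "slide001", seed = 1)
  truth <- true_object_centers(sl2)
  scores <- roi_detection_scores(sv$rois, truth)
  expect_gte(scores["recall"], 0.9)

  # fewer live-view frames than a full-resolution stored-tile pass would use
  cam <- camera_model()
  obj5 <- objective_from_camera(cam, 5)
  cs <- sl2$spec$coverslip
  full_plan <- plan_tiles(region(cs$x_um, cs$y_um, cs$w_um, cs$h_um), obj5,
                          cfg2$phase1$overlap_frac)
  expect_lte(sv$n_frames, nrow(full_plan$centers))
})

test_that("the two-phase workflow runs end to end on a small pool", {
  cfg <- small_config(n_objects = 10, seed = 5)
  st <- wf_store(withr::local_tempdir())
  pool <- simulate_slide_pool(st, 2, cfg)
  r1 <- run_phase1(st, cfg)
  expect_equal(as.integer(r1$summary["SUCCESS"]), 6)
  rois1 <- utils::read.csv(file.path(st$path, "rois", "slide001.csv"))
  expect_gt(nrow(rois1), 0)
  expect_true(all(rois1$source == "survey"))

  r2 <- run_phase2(st, cfg)
  expect_equal(as.integer(r2$summary["SUCCESS"]), 6)
  for (sid in pool$slide_id) {
    cp <- phase2_capture(st, sid)
    expect_gte(cp$rate, 0.9)
  }

  # the calibration recovered the relative pose change of slide001
  p1 <- jsonlite::fromJSON(file.path(st$path, "calib", "slide001_phase1.json"))
  p2 <- jsonlite::fromJSON(file.path(st$path, "calib", "slide001_phase2.json"))
  true_dx <- p2$pose$dx_um - p1$pose$dx_um
  expect_lt(abs(p2$correction$dx_um - true_dx), 2)

  # multi-tile ROIs got stitched composites; single-field ROIs one image
  ent <- scopeflow:::read_meta(st$path, "slide001", "phase2")$entries
  per_roi <- table(ent$roi_label)
  if (any(per_roi > 1)) {
    stitched <- scopeflow:::read_meta(st$path, "slide001", "phase2_stitched")$entries
    expect_true(all(names(per_roi)[per_roi > 1] %in% stitched$roi_label))
  }
  if (any(per_roi == 1)) expect_true(min(per_roi) == 1)
})

test_that("a phase-1 interruption resumes with only the remaining slides", {
  cfg <- small_config(n_objects = 5, seed = 6)
  st <- wf_store(withr::local_tempdir())
  simulate_slide_pool(st, 2, cfg)
  r1 <- run_phase1(st, cfg, interrupt_after = 3)   # survey of slide001 done
  expect_true(r1$interrupted)
  tt <- wf_tasks(st)
  expect_equal(sum(tt$status == "SUCCESS"), 3)
  sv_tile <- file.path(st$path, "data", "slide001", "survey", "tile_00001.tif")
  expect_true(file.exists(sv_tile))
  mt1 <- file.info(sv_tile)$mtime
  r2 <- run_phase1(st, cfg)
  tt2 <- wf_tasks(st)
  expect_true(all(tt2$status == "SUCCESS"))
  # slide001 imagery untouched by the resumed run (not re-acquired)
  expect_identical(file.info(sv_tile)$mtime, mt1)
  expect_true(file.exists(file.path(st$path, "rois", "slide002.csv")))
})

test_that("manual loading defers until the operator acknowledges", {
  cfg <- small_config(n_objects = 3, seed = 8)
  cfg$loader$mode <- "manual_prompt"
  st <- wf_store(withr::local_tempdir())
  simulate_slide_pool(st, 1, cfg)
  r1 <- run_phase1(st, cfg)
  tt <- wf_tasks(st)
  expect_equal(tt$status[tt$module == "p1_load"], "DEFER")
  wf_acknowledge(st, tt$task_id[tt$module == "p1_load"])
  r2 <- run_phase1(st, cfg)
  expect_true(all(wf_tasks(st)$status == "SUCCESS"))
})
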
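# The two-phase acquisition workflow over a pool of slides: slide loading
# (automatic or operator-prompted), tiled or live-view survey imaging,
# object detection, slide reload with frosted-edge re-calibration, and
# high-magnification per-ROI re-imaging with autofocus and stitching.

#' Create a slide pool
#'
#' @param slide_ids Character vector of unique slide identifiers.
#' @param experiment_id Experiment tag carried on every slide.
#' @return A data frame with `slide_id`, `cartridge_position`,
#'   `experiment_id`, `status` (all `"PENDING"`).
#' @export
slide_pool <- function(slide_ids, experiment_id = "exp1") {
  if (anyDuplicated(slide_ids))
    sf_stop("sf_pool_error", "slide ids must be unique")
  data.frame(slide_id = as.character(slide_ids),
             cartridge_position = seq_along(slide_ids),
             experiment_id = experiment_id, status = "PENDING")
}

#' Simulate a pool of slides under a store
#'
#' Generates `n` synthetic slides from the configured slide model (each
#' with its own seed), writes their ground truth under `<store>/slides/`,
#' and records the pool table.
#'
#' @param store An [wf_store()].
#' @param n Number of slides.
#' @param config Run configuration (see [default_config()]).
#' @return The pool data frame.
#' @export
simulate_slide_pool <- function(store, n, config = default_config()) {
  ids <- sprintf("slide%03d", seq_len(n))
  pool <- slide_pool(ids)
  dir.create(file.path(store$path, "slides"), showWarnings = FALSE)
  for (i in seq_len(n)) {
    sp <- config_slide_spec(config, seed = config$seed * 1000L + i)
    write_slide(make_slide(sp), file.path(store$path, "slides", paste0(ids[i], ".json")))
  }
  utils::write.csv(pool, file.path(store$path, "pool.csv"), row.names = FALSE)
  pool
}

read_pool <- function(store) {
  fp <- file.path(store$path, "pool.csv")
  if (!file.exists(fp)) sf_stop("sf_pool_error", "no slide pool under %s", store$path)
  utils::read.csv(fp)
}

slide_path <- function(store, slide_id) {
  file.path(store$path, "slides", paste0(slide_id, ".json"))
}

#' Load the next pending slide from a pool
#'
#' In `"auto"` mode the virtual slide loader seats the slide with seeded
#' pose noise and the pool status advances to `"LOADED"`. In
#' `"manual_prompt"` mode the caller is expected to park the task in
#' `DEFER` until the operator acknowledges (see the workflow engine); this
#' function then behaves as auto once invoked. An exhausted pool returns
#' `NULL` (normal end-of-pool signal).
#'
#' @param pool Pool data frame.
#' @param store An [wf_store()] holding the slide fixtures.
#' @param config Run configuration.
#' @param seed Seed for the seating pose.
#' @return `NULL`, or a list with `slide` (posed `sf_slide`), `slide_id`,
#'   and the updated `pool`.
#' @export
load_next <- function(pool, store, config = default_config(), seed = NULL) {
  idx <- which(pool$status == "PENDING")
  if (!length(idx)) return(NULL)
  i <- idx[order(pool$cartridge_position[idx])][1]
  sid <- pool$slide_id[i]
  slide <- read_slide(slide_path(store, sid))
  slide <- load_slide(slide, sd_um = config$loader$sd_um,
                      sd_rad = config$loader$sd_rad, seed = seed)
  pool$status[i] <- "LOADED"
  list(slide = slide, slide_id = sid, pool = pool)
}

phase_objective <- function(config, phase) {
  cam <- config_camera(config)
  mag <- if (phase == 1) config$phase1$magnification else config$phase2$magnification
  objective_from_camera(cam, mag)
}

#' Acquire a tiled image pass over a region
#'
#' Plans the tiling, optionally autofocuses, renders each field with the
#' simulated microscope and stores it through the dataset writer. The pass
#' is resumable at tile granularity: tiles already present in the metadata
#' are skipped, so each tile is acquired exactly once across interrupted
#' and resumed runs.
#'
#' @param slide A posed `sf_slide`.
#' @param reg The [region()] to cover (stage frame).
#' @param objective,camera Imaging configuration.
#' @param root Dataset root directory.
#' @param slide_id,pass Dataset coordinates.
#' @param overlap_frac Tile overlap fraction.
#' @param z_um Focus position used for every tile (`NULL` = true focus).
#' @param seed Base seed; tile k renders with `seed + k`.
#' @param interrupt_after_tiles Simulate a crash after this many newly
#'   rendered tiles (testing hook).
#' @return A list with `plan`, `n_rendered`, `n_total`.
#' @export
image_region <- function(slide, reg, objective, camera, root, slide_id, pass,
                         overlap_frac = 0.1, z_um = NULL, seed = 1L,
                         interrupt_after_tiles = NULL) {
  sb <- slide_bounds_stage(slide)
  if (reg$x_um < sb$x_um - 1e-6 || reg$y_um < sb$y_um - 1e-6 ||
      reg$x_um + reg$w_um > sb$x_um + sb$w_um + 1e-6 ||
      reg$y_um + reg$h_um > sb$y_um + sb$h_um + 1e-6)
    sf_stop("sf_out_of_bounds", "acquisition region exceeds the slide")
  plan <- plan_tiles(reg, objective, overlap_frac)
  open_pass(root, slide_id, pass, objective, camera, resume = TRUE)
  done <- read_meta(root, slide_id, pass)$entries$tile_index
  rendered <- 0L
  for (k in seq_len(nrow(plan$centers))) {
    if (k %in% done) next
    ctr <- stage_point(plan$centers$x_um[k], plan$centers$y_um[k])
    img <- render_field(slide, ctr, objective, camera, z_um = z_um,
                        seed = seed + k)
    write_tile(root, slide_id, pass, k, img, ctr, z_um = z_um %||% NA_real_,
               seed = seed + k)
    rendered <- rendered + 1L
    if (!is.null(interrupt_after_tiles) && rendered >= interrupt_after_tiles &&
        k < nrow(plan$centers))
      sf_interrupt()
  }
  list(plan = plan, n_rendered = rendered, n_total = nrow(plan$centers))
}

# axis-aligned stage-frame bounding box of the (posed) slide
slide_bounds_stage <- function(slide) {
  sp <- slide$spec
  corners <- rbind(c(0, 0), c(sp$width_um, 0), c(0, sp$height_um),
                   c(sp$width_um, sp$height_um))
  pc <- apply_offset(corners, slide$pose, slide_center(slide))
  region(min(pc[, 1]), min(pc[, 2]),
         max(pc[, 1]) - min(pc[, 1]), max(pc[, 2]) - min(pc[, 2]))
}

#' Survey a slide from live view and detect objects
#'
#' Sweeps the region with downsampled live-view frames on a coarse grid
#' (no autofocus, no per-frame storage), assembles a stage-placed survey
#' mosaic, and runs the object detector on it. Survey ROIs are marked
#' `source = "survey"`; survey and re-imaging can then share one
#' imaging modality.
#'
#' @param slide A posed `sf_slide`.
#' @param reg The [region()] to sweep (defaults to the coverslip region,
#'   stage frame).
#' @param config Run configuration.
#' @param slide_id Identifier stamped on detected ROIs.
#' @param seed Base seed for the survey frames.
#' @return A list with `mosaic`, `mapping`, `rois`, `n_frames`, `umpp`.
#' @export
survey_slide <- function(slide, reg = NULL, config = default_config(),
                         slide_id = "slide", seed = 1L) {
  cam <- config_camera(config)
  objv <- phase_objective(config, 1)
  if (is.null(reg)) {
    cs <- slide$spec$coverslip
    reg <- region(cs$x_um, cs$y_um, cs$w_um, cs$h_um)
  }
  ds <- as.integer(config$phase1$downsample)
  umpp <- cam$ref_um_per_px_at_1x / objv$magnification
  umpp_s <- umpp * ds
  plan <- plan_tiles(reg, objv, config$phase1$survey_overlap_frac)
  W <- ceiling(reg$w_um / umpp_s); H <- ceiling(reg$h_um / umpp_s)
  mosaic <- matrix(slide$spec$background_level, H, W)
  for (k in seq_len(nrow(plan$centers))) {
    ctr <- stage_point(plan$centers$x_um[k], plan$centers$y_um[k])
    fr <- survey_frame(slide, ctr, objv, cam, downsample = ds, seed = seed + k)
    fm <- field_mapping(ctr, objv, cam)
    tl <- pixel_to_stage(c(0, 0), fm)      # stage position of pixel (0,0)
    c0 <- round((tl$x_um - reg$x_um) / umpp_s)
    r0 <- round((tl$y_um - reg$y_um) / umpp_s)
    rr <- (r0 + 1L):(r0 + nrow(fr)); cc <- (c0 + 1L):(c0 + ncol(fr))
    okr <- rr >= 1 & rr <= H; okc <- cc >= 1 & cc <= W
    mosaic[rr[okr], cc[okc]] <- fr[okr, okc]
  }
  mapping <- camera_mapping(umpp_s, umpp_s,
                            origin = stage_point(reg$x_um + umpp_s / 2,
                                                 reg$y_um + umpp_s / 2))
  params <- config_detection(config)
  seg <- segment_objects(mosaic, params, mapping)
  rois <- components_to_rois(seg, mapping, params, slide_id, source = "survey",
                             slide_bounds = slide_bounds_stage(slide))
  rois <- merge_rois(rois, params$merge_overlap_frac)
  list(mosaic = mosaic, mapping = mapping, rois = rois,
       n_frames = nrow(plan$centers), umpp = umpp_s, region = reg)
}

# store the survey mosaic as a single-tile pass whose metadata reconstructs
# the mosaic mapping (pseudo-objective at magnification 1)
write_survey_pass <- function(root, slide_id, mosaic, reg, umpp_s) {
  H <- nrow(mosaic); W <- ncol(mosaic)
  cam <- camera_model(W, H, ref_um_per_px_at_1x = umpp_s, read_noise_sd = 0)
  objv <- objective("survey", 1, W * umpp_s, H * umpp_s)
  # pixel (0,0) center sits half a survey pixel inside the region corner
  ctr <- stage_point(reg$x_um + umpp_s / 2 + (W - 1) / 2 * umpp_s,
                     reg$y_um + umpp_s / 2 + (H - 1) / 2 * umpp_s)
  open_pass(root, slide_id, "survey", objv, cam, resume = TRUE)
  done <- read_meta(root, slide_id, "survey")$entries$tile_index
  if (!(1L %in% done))
    write_tile(root, slide_id, "survey", 1L, mosaic, ctr)
  invisible(NULL)
}

#' Measure and persist the calibration reference for a loaded slide
#'
#' Locates the frosted-band edge (x) and the slide's long top edge (y) at
#' the phase-1 objective and records their apparent stage positions. The
#' phase-2 reload repeats the measurement and the difference yields the
#' pose correction.
#'
#' @keywords internal
measure_edges <- function(slide, config, seed = 1L) {
  cam <- config_camera(config)
  objv <- phase_objective(config, 1)
  sp <- slide$spec
  ys <- seq(sp$height_um * 0.3, sp$height_um * 0.7,
            length.out = max(1L, config$calibration$n_observations))
  xobs <- lapply(seq_along(ys), function(i)
    locate_edge(slide, stage_point(sp$frosted_band_w_um, ys[i]), objv, cam,
                axis = "x",
                accept_confidence = config$calibration$accept_confidence,
                seed = seed + i))
  xcal <- mean(vapply(xobs, function(o) o$found_edge_um, numeric(1))[
    vapply(xobs, function(o) !o$flat && o$confidence >= config$calibration$confidence_floor, TRUE)])
  gx <- (sp$frosted_band_w_um + sp$coverslip$x_um) / 2   # clear glass strip
  fov_h <- cam$sensor_h_px * cam$ref_um_per_px_at_1x / objv$magnification
  yobs <- locate_edge(slide, stage_point(gx, fov_h * 0.25),
                      objv, cam, axis = "y",
                      accept_confidence = config$calibration$accept_confidence,
                      seed = seed + 97L)
  if (!is.finite(xcal))
    sf_stop("sf_calibration_error", "frosted-edge calibration failed")
  list(edge_x_um = xcal,
       edge_y_um = if (yobs$flat) NA_real_ else yobs$found_edge_um,
       x_observations = xobs, y_observation = yobs)
}

#' Run phase 1 (survey and detection) over a slide pool
#'
#' For each slide: load with seeded seating noise, survey (live view) or
#' tiled imaging at the low-magnification objective, detect and merge ROIs,
#' and persist the ROI table together with the slide's phase-1 calibration
#' reference. Execution and resume are driven by the workflow engine; one
#' slide's failure does not block the others.
#'
#' @param store An [wf_store()] with a simulated pool (see
#'   [simulate_slide_pool()]).
#' @param config Run configuration.
#' @param workers Concurrent compute tasks.
#' @param interrupt_after Abort after this many task completions (testing).
#' @return The run log from the workflow engine.
#' @export
run_phase1 <- function(store, config = default_config(), workers = 2L,
                       interrupt_after = NULL) {
  pool <- read_pool(store)
  wid <- ensure_workflow(store, config)
  ctx <- list(config = config, interrupt_after = interrupt_after)
  wf_resume(store, wid, "phase1", pool$slide_id, workers = workers, ctx = ctx)
}

#' Run phase 2 (reload, calibrate, re-image) over a slide pool
#'
#' For each slide: reload (fresh seating pose), re-locate the frosted-band
#' and top edges, convert the displacement into an offset correction,
#' correct and pad the stored phase-1 ROIs, plan high-magnification tiles
#' per ROI (multi-tile ROIs are stitched into composites), autofocus per
#' the configured policy, and store all fields.
#'
#' @inheritParams run_phase1
#' @export
run_phase2 <- function(store, config = default_config(), workers = 2L,
                       interrupt_after = NULL) {
  pool <- read_pool(store)
  wid <- ensure_workflow(store, config)
  ctx <- list(config = config, interrupt_after = interrupt_after)
  wf_resume(store, wid, "phase2", pool$slide_id, workers = workers, ctx = ctx)
}

ensure_workflow <- function(store, config) {
  g <- two_phase_graph(config)
  wf_persist(g, store)
}

#' The canonical two-phase workflow graph
#'
#' Modules: phase-1 load -> image/survey -> detect; phase-2 reload+calibrate
#' -> re-image -> stitch. Entry point `"phase1"` runs the first chain,
#' `"phase2"` resumes at the reload step.
#'
#' @param config Run configuration (stored in the module configs).
#' @export
two_phase_graph <- function(config = default_config()) {
  cfg <- list(digest = params_digest(config))
  wf_graph(list(
    wf_module("p1_load", "acquisition", "sf_p1_load", cfg),
    wf_module("p1_image", "acquisition", "sf_p1_image", cfg),
    wf_module("p1_detect", "compute", "sf_p1_detect", cfg),
    wf_module("p2_reload", "acquisition", "sf_p2_reload", cfg),
    wf_module("p2_image", "acquisition", "sf_p2_image", cfg),
    wf_module("p2_stitch", "compute", "sf_p2_stitch", cfg)),
    data.frame(parent = c("p1_load", "p1_image", "p2_reload", "p2_image"),
               child = c("p1_image", "p1_detect", "p2_image", "p2_stitch")),
    entry_points = list(phase1 = "p1_load", phase2 = "p2_reload"))
}

# slide-indexed deterministic seeds below 2^31
slide_seed <- function(config, slide_id, salt) {
  base <- (config$seed %% 100000L) * 10000L
  idx <- as.integer(sub("[^0-9]*", "", slide_id))
  if (is.na(idx)) idx <- sum(utf8ToInt(slide_id))
  (base + idx * 131L + salt) %% .Machine$integer.max
}

# ---- workflow entry functions --------------------------------------------

sf_p1_load <- function(task, ctx) {
  store <- ctx$store; config <- ctx$config
  sid <- task$slide_id
  if (identical(config$loader$mode, "manual_prompt") &&
      !isTRUE(task$acknowledged))
    return(list(status = "DEFER"))
  slide <- read_slide(slide_path(store, sid))
  slide <- load_slide(slide, config$loader$sd_um, config$loader$sd_rad,
                      seed = slide_seed(config, sid, 1L))
  write_slide(slide, slide_path(store, sid))
  cal <- measure_edges(slide, config, seed = slide_seed(config, sid, 2L))
  dir.create(file.path(store$path, "calib"), showWarnings = FALSE)
  jsonlite::write_json(list(edge_x_um = cal$edge_x_um, edge_y_um = cal$edge_y_um,
                            pose = unclass(slide$pose)),
                       file.path(store$path, "calib", paste0(sid, "_phase1.json")),
                       auto_unbox = TRUE, digits = NA, na = "null")
  list(status = "SUCCESS")
}

sf_p1_image <- function(task, ctx) {
  store <- ctx$store; config <- ctx$config
  sid <- task$slide_id
  slide <- read_slide(slide_path(store, sid))
  seed <- slide_seed(config, sid, 3L)
  cs <- slide$spec$coverslip
  reg <- region(cs$x_um, cs$y_um, cs$w_um, cs$h_um)
  if (identical(config$phase1$survey_mode, "live_view")) {
    sv <- survey_slide(slide, reg, config, slide_id = sid, seed = seed)
    write_survey_pass(store$path, sid, sv$mosaic, reg, sv$umpp)
    dir.create(file.path(store$path, "rois"), showWarnings = FALSE)
    utils::write.csv(rois_to_df(sv$rois),
                     file.path(store$path, "rois", paste0(sid, ".csv")),
                     row.names = FALSE)
    list(status = "SUCCESS", result_uri = sprintf("rois/%s.csv", sid))
  } else {
    cam <- config_camera(config)
    objv <- phase_objective(config, 1)
    image_region(slide, reg, objv, cam, store$path, sid, "phase1",
                 overlap_frac = config$phase1$overlap_frac, seed = seed,
                 interrupt_after_tiles = ctx$interrupt_after_tiles)
    list(status = "SUCCESS", result_uri = sprintf("data/%s/phase1", sid))
  }
}

sf_p1_detect <- function(task, ctx) {
  store <- ctx$store; config <- ctx$config
  sid <- task$slide_id
  roi_file <- file.path(store$path, "rois", paste0(sid, ".csv"))
  if (identical(config$phase1$survey_mode, "live_view")) {
    # detection already ran on the survey mosaic inside the survey sweep
    if (!file.exists(roi_file))
      sf_stop("sf_roi_error", "survey produced no ROI table for %s", sid)
    return(list(status = "SUCCESS", result_uri = sprintf("rois/%s.csv", sid)))
  }
  slide <- read_slide(slide_path(store, sid))
  params <- config_detection(config)
  ds <- read_dataset(store$path, sid, "phase1")
  all_rois <- list()
  for (t in ds$tiles) {
    seg <- segment_objects(t$image, params, t$mapping)
    rois <- components_to_rois(seg, t$mapping, params, sid,
                               source = "phase1_tiles",
                               slide_bounds = slide_bounds_stage(slide))
    all_rois <- c(all_rois, rois)
  }
  merged <- merge_rois(all_rois, params$merge_overlap_frac)
  dir.create(file.path(store$path, "rois"), showWarnings = FALSE)
  utils::write.csv(rois_to_df(merged), roi_file, row.names = FALSE)
  list(status = "SUCCESS", result_uri = sprintf("rois/%s.csv", sid))
}

sf_p2_reload <- function(task, ctx) {
  store <- ctx$store; config <- ctx$config
  sid <- task$slide_id
  ref_file <- file.path(store$path, "calib", paste0(sid, "_phase1.json"))
  if (!file.exists(ref_file))
    sf_stop("sf_calibration_error", "no phase-1 calibration reference for %s", sid)
  ref <- jsonlite::fromJSON(ref_file)
  if (identical(config$loader$mode, "manual_prompt") &&
      !isTRUE(task$acknowledged))
    return(list(status = "DEFER"))
  slide <- read_slide(slide_path(store, sid))
  slide <- load_slide(slide, config$loader$sd_um, config$loader$sd_rad,
                      seed = slide_seed(config, sid, 11L))
  write_slide(slide, slide_path(store, sid))
  cal <- measure_edges(slide, config, seed = slide_seed(config, sid, 12L))
  corr_x <- estimate_offset(ref$edge_x_um, cal$x_observations,
                            confidence_floor = config$calibration$confidence_floor,
                            estimate_rotation = config$calibration$estimate_rotation,
                            axis = "x")
  dy <- if (is.finite(cal$edge_y_um) && !is.null(ref$edge_y_um) &&
            is.finite(ref$edge_y_um)) cal$edge_y_um - ref$edge_y_um else 0
  corr <- offset_correction(corr_x$dx_um, dy, corr_x$rot_rad)
  jsonlite::write_json(list(correction = unclass(corr), pose = unclass(slide$pose)),
                       file.path(store$path, "calib", paste0(sid, "_phase2.json")),
                       auto_unbox = TRUE, digits = NA, na = "null")
  list(status = "SUCCESS")
}

# padded, corrected phase-2 target box for one stored ROI
phase2_target <- function(roi_row, corr, pad_frac) {
  x0 <- roi_row$x_um + corr$dx_um; y0 <- roi_row$y_um + corr$dy_um
  w <- roi_row$w_um; h <- roi_row$h_um
  region(x0 - pad_frac * w, y0 - pad_frac * h,
         w * (1 + 2 * pad_frac), h * (1 + 2 * pad_frac))
}

sf_p2_image <- function(task, ctx) {
  store <- ctx$store; config <- ctx$config
  sid <- task$slide_id
  slide <- read_slide(slide_path(store, sid))
  corr_l <- jsonlite::fromJSON(file.path(store$path, "calib",
                                         paste0(sid, "_phase2.json")))$correction
  corr <- offset_correction(corr_l$dx_um, corr_l$dy_um, corr_l$rot_rad)
  rois <- utils::read.csv(file.path(store$path, "rois", paste0(sid, ".csv")))
  cam <- config_camera(config)
  objv <- phase_objective(config, 2)
  seed <- slide_seed(config, sid, 13L)
  af <- config$phase2$autofocus
  z_best <- NULL
  open_pass(store$path, sid, "phase2", objv, cam, resume = TRUE)
  done <- read_meta(store$path, sid, "phase2")$entries
  tile_no <- 0L
  rendered <- 0L
  for (r in seq_len(nrow(rois))) {
    target <- phase2_target(rois[r, ], corr, config$phase2$pad_frac)
    plan <- plan_tiles(target, objv, config$phase2$overlap_frac)
    # focus once per slide (policy per_slide) or per ROI, evaluated on a
    # full field at the ROI center: the object's sharp boundary, not just
    # its smooth interior texture, must fall inside the scored crop
    if (isTRUE(af$enabled) && (is.null(z_best) || identical(af$policy, "per_roi"))) {
      ctr1 <- stage_point(target$x_um + target$w_um / 2,
                          target$y_um + target$h_um / 2)
      afc <- focus_search_config(as.numeric(af$z_range_um), af$coarse_step_um,
                                 af$fine_step_um, af$metric, af$crop_frac)
      res <- autofocus_search(function(z)
        render_field(slide, ctr1, objv, cam, z_um = z, seed = seed),
        afc)
      z_best <- res$best_z_um
    }
    z_use <- if (isTRUE(af$enabled)) z_best else NULL
    for (k in seq_len(nrow(plan$centers))) {
      tile_no <- tile_no + 1L
      if (tile_no %in% done$tile_index) next
      ctr <- stage_point(plan$centers$x_um[k], plan$centers$y_um[k])
      img <- render_field(slide, ctr, objv, cam, z_um = z_use,
                          seed = seed + tile_no)
      write_tile(store$path, sid, "phase2", tile_no, img, ctr,
                 z_um = z_use %||% NA_real_, seed = seed + tile_no,
                 roi_label = rois$label[r])
      rendered <- rendered + 1L
      if (!is.null(ctx$interrupt_after_tiles) && rendered >= ctx$interrupt_after_tiles)
        sf_interrupt()
    }
  }
  list(status = "SUCCESS", result_uri = sprintf("data/%s/phase2", sid))
}

sf_p2_stitch <- function(task, ctx) {
  store <- ctx$store; config <- ctx$config
  sid <- task$slide_id
  meta <- read_meta(store$path, sid, "phase2")
  if (is.null(meta))
    sf_stop("sf_dataset_error", "no phase-2 pass for slide %s", sid)
  ent <- meta$entries
  labels <- unique(ent$roi_label)
  open_pass(store$path, sid, "phase2_stitched",
            objective(meta$objective$name, meta$objective$magnification,
                      meta$objective$fov_w_um, meta$objective$fov_h_um),
            resume = TRUE)
  done <- read_meta(store$path, sid, "phase2_stitched")$entries
  out_no <- 0L
  for (lb in labels) {
    out_no <- out_no + 1L
    if (out_no %in% done$tile_index) next
    idx <- which(ent$roi_label == lb)
    if (length(idx) == 1) next   # single-field ROI: the acquired tile IS the composite
    # tiles for one ROI are read lazily; whole-pass reads would not scale
    tiles <- lapply(ent$tile_index[idx], function(ti)
      read_tile(store$path, sid, "phase2", ti))
    for (k in seq_along(tiles)) tiles[[k]]$tile_index <- k
    {
      # rebuild the per-ROI grid plan implied by the tile centers
      xs <- sort(unique(round(vapply(tiles, function(t) t$nominal_center$x_um, 1), 3)))
      ys <- sort(unique(round(vapply(tiles, function(t) t$nominal_center$y_um, 1), 3)))
      centers <- data.frame(
        index = seq_along(tiles),
        row = vapply(tiles, function(t) which.min(abs(ys - t$nominal_center$y_um)), 1L),
        col = vapply(tiles, function(t) which.min(abs(xs - t$nominal_center$x_um)), 1L),
        x_um = vapply(tiles, function(t) t$nominal_center$x_um, 1),
        y_um = vapply(tiles, function(t) t$nominal_center$y_um, 1))
      plan <- structure(list(centers = centers), class = "sf_tile_plan")
      off <- pairwise_offsets(tiles, plan,
                              confidence_floor = config$stitch$confidence_floor,
                              margin_px = config$stitch$margin_px)
      lay <- global_place(tiles, off)
      mos <- render_mosaic(tiles, lay, blend = config$stitch$blend)
      comp <- mos$image
      umpp <- tiles[[1]]$mapping$um_per_px_x
      ctr <- stage_point((mos$origin_px[1] + ncol(comp) / 2) * umpp,
                         (mos$origin_px[2] + nrow(comp) / 2) * umpp)
    }
    write_tile(store$path, sid, "phase2_stitched", out_no, comp, ctr,
               roi_label = lb)
  }
  list(status = "SUCCESS", result_uri = sprintf("data/%s/phase2_stitched", sid))
}

# ---- imaging economy ------------------------------------------------------

#' Imaging-cost summary of the two-phase strategy
#'
#' Pure arithmetic on plans: the exhaustive high-resolution baseline is the
#' phase-1 tile count times the squared magnification ratio (each
#' low-magnification field holds ratio^2 high-magnification fields at zero
#' overlap); the economy ratio compares it against the acquired counts with
#' a low-magnification field weighted as 1/ratio^2 of a high-magnification
#' field.
#'
#' @param phase1_tiles Phase-1 tile count, or an `sf_tile_plan`.
#' @param phase2_tiles Acquired high-magnification field count, or a list
#'   of `sf_tile_plan` (one per ROI).
#' @param mag1,mag2 The two magnifications (or [objective()] objects).
#' @return A list with `n_lowres_images`, `n_highres_images`,
#'   `n_exhaustive_highres`, `economy_ratio`.
#' @export
imaging_cost <- function(phase1_tiles, phase2_tiles, mag1 = 5, mag2 = 20) {
  n1 <- if (inherits(phase1_tiles, "sf_tile_plan")) nrow(phase1_tiles$centers)
        else as.integer(phase1_tiles)
  n2 <- if (is.list(phase2_tiles))
    sum(vapply(phase2_tiles, function(p)
      if (inherits(p, "sf_tile_plan")) nrow(p$centers) else as.integer(p), 1L))
  else as.integer(phase2_tiles)
  m1 <- if (inherits(mag1, "sf_objective")) mag1$magnification else mag1
  m2 <- if (inherits(mag2, "sf_objective")) mag2$magnification else mag2
  ratio <- m2 / m1
  n_ex <- round(n1 * ratio^2)
  acquired_equiv <- n2 + n1 / ratio^2
  structure(list(n_lowres_images = n1, n_highres_images = n2,
                 n_exhaustive_highres = n_ex,
                 economy_ratio = if (acquired_equiv > 0) n_ex / acquired_equiv else Inf),
            class = "sf_imaging_cost")
}

#' @export
print.sf_imaging_cost <- function(x, ...) {
  cat(sprintf(paste0("<imaging cost: %d low-res + %d high-res acquired; ",
                     "exhaustive high-res baseline %d; economy %.1f-fold>\n"),
              x$n_lowres_images, x$n_highres_images, x$n_exhaustive_highres,
              x$economy_ratio))
  invisible(x)
}

#' Fraction of ground-truth objects captured by acquired phase-2 fields
#'
#' Scores an end-to-end run against the simulator's ground truth: an object
#' counts as captured when its true (posed) center falls inside at least one
#' acquired phase-2 field.
#'
#' @param store An [wf_store()] after [run_phase2()].
#' @param slide_id Slide to score.
#' @return A list with `captured`, `total`, `rate`.
#' @export
phase2_capture <- function(store, slide_id) {
  slide <- read_slide(slide_path(store, slide_id))
  truth <- true_object_centers(slide)
  meta <- read_meta(store$path, slide_id, "phase2")
  if (is.null(meta))
    sf_stop("sf_dataset_error", "no phase-2 pass for slide %s", slide_id)
  ent <- meta$entries
  fw <- meta$objective$fov_w_um / 2; fh <- meta$objective$fov_h_um / 2
  captured <- vapply(seq_len(nrow(truth)), function(i)
    any(abs(ent$x_um - truth[i, 1]) <= fw & abs(ent$y_um - truth[i, 2]) <= fh),
    TRUE)
  list(captured = sum(captured), total = nrow(truth),
       rate = if (nrow(truth)) mean(captured) else NA_real_)
}

#' Run a complete two-phase imaging study over independent slides
#'
#' Convenience driver for benchmark studies: each slide gets its own store,
#' runs phase 1 (live-view survey and detection) and phase 2 (reload,
#' calibration, high-magnification re-imaging, stitching), and is scored
#' against the simulator's ground truth. Slides are processed sequentially
#' and their image data can be deleted after scoring to bound disk use.
#'
#' @param n_slides Number of slides in the study.
#' @param config Run configuration (see [default_config()]); `config$seed`
#'   drives every source of randomness.
#' @param root Directory for the per-slide stores.
#' @param keep_data Keep image data on disk after scoring.
#' @return A list with `per_slide` (one row per slide: ROI count, detection
#'   recall/precision, capture rate, calibration errors, tile counts) and
#'   `totals` (object-weighted aggregates plus the imaging-cost summary).
#' @export
run_two_phase_study <- function(n_slides = 8, config = default_config(),
                                root = tempfile("sf_study"),
                                keep_data = FALSE) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(n_slides)) {
    cfg <- config
    cfg$seed <- as.integer((config$seed + (i - 1)) %% .Machine$integer.max)
    st <- wf_store(file.path(root, sprintf("slide_run_%03d", i)))
    simulate_slide_pool(st, 1, cfg)
    sid <- "slide001"
    run_phase1(st, cfg)
    slide <- read_slide(slide_path(st, sid))
    rois <- df_to_rois(utils::read.csv(file.path(st$path, "rois",
                                                 paste0(sid, ".csv"))))
    truth_p1 <- true_object_centers(slide)
    in_box <- function(pt, r)
      pt[1] >= r$bbox$x_um && pt[1] <= r$bbox$x_um + r$bbox$w_um &&
      pt[2] >= r$bbox$y_um && pt[2] <= r$bbox$y_um + r$bbox$h_um
    hit_obj <- vapply(seq_len(nrow(truth_p1)), function(k)
      any(vapply(rois, function(r) in_box(truth_p1[k, ], r), TRUE)), TRUE)
    hit_roi <- vapply(rois, function(r)
      any(vapply(seq_len(nrow(truth_p1)), function(k)
        in_box(truth_p1[k, ], r), TRUE)), TRUE)

    run_phase2(st, cfg)
    cap <- phase2_capture(st, sid)
    p1 <- jsonlite::fromJSON(file.path(st$path, "calib", paste0(sid, "_phase1.json")))
    p2 <- jsonlite::fromJSON(file.path(st$path, "calib", paste0(sid, "_phase2.json")))
    meta2 <- read_meta(st$path, sid, "phase2")
    sv_meta <- read_meta(st$path, sid, "survey")
    cs <- slide$spec$coverslip
    cam <- config_camera(cfg)
    obj1 <- phase_objective(cfg, 1)
    n_frames <- nrow(plan_tiles(region(cs$x_um, cs$y_um, cs$w_um, cs$h_um),
                                obj1, cfg$phase1$survey_overlap_frac)$centers)
    rows[[i]] <- data.frame(
      slide = i,
      n_objects = nrow(truth_p1),
      n_rois = length(rois),
      detected = sum(hit_obj),
      n_roi_hits = sum(hit_roi),
      captured = cap$captured,
      n_lowres = n_frames,
      n_highres = nrow(meta2$entries),
      calib_dx_err_um = p2$correction$dx_um - (p2$pose$dx_um - p1$pose$dx_um),
      calib_dy_err_um = p2$correction$dy_um - (p2$pose$dy_um - p1$pose$dy_um))
    if (!keep_data) unlink(file.path(st$path, "data"), recursive = TRUE)
  }
  per_slide <- do.call(rbind, rows)
  cost <- imaging_cost(sum(per_slide$n_lowres), sum(per_slide$n_highres),
                       config$phase1$magnification, config$phase2$magnification)
  totals <- list(
    n_objects = sum(per_slide$n_objects),
    detection_recall = sum(per_slide$detected) / sum(per_slide$n_objects),
    detection_precision = sum(per_slide$n_roi_hits) / sum(per_slide$n_rois),
    capture_rate = sum(per_slide$captured) / sum(per_slide$n_objects),
    imaging_cost = cost)
  list(per_slide = per_slide, totals = totals)
}
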